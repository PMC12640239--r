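# Steady-state kinetic simulation.
#
# The mass-balance system is dC/dt = S v(C) + influx, with mass-action
# rates v = k * prod(substrates) and single-substrate Michaelis-Menten
# rates v = Vmax*C/(Km+C); sink reactions are first-order removals.

# flatten a network into an evaluation plan: per-reaction index vectors and
# one parameter vector theta (reaction params then influx rates)
buildPlan <- function(net) {
    nodes <- net@nodes
    n <- length(nodes)
    theta <- numeric(0)
    rx <- lapply(net@reactions, function(r) {
        off <- length(theta)
        theta <<- c(theta, r@params)
        list(law = r@law, sub = match(r@substrates, nodes),
             prod = match(r@products, nodes), off = off)
    })
    influxIdx <- match(names(net@influx), nodes)
    list(n = n, nodes = nodes, rx = rx,
         theta = c(theta, unname(net@influx)), nRxPar = length(theta),
         influxIdx = influxIdx)
}

# time-derivative of concentrations under a (possibly perturbed) theta
planRates <- function(plan, C, theta) {
    dC <- numeric(plan$n)
    Cpos <- pmax(C, 0)
    for (r in plan$rx) {
        v <- if (r$law == "mass_action")
            theta[r$off + 1L] * prod(Cpos[r$sub])
        else {
            s <- Cpos[r$sub]
            theta[r$off + 1L] * s / (theta[r$off + 2L] + s)
        }
        dC[r$sub] <- dC[r$sub] - v
        if (length(r$prod)) dC[r$prod] <- dC[r$prod] + v
    }
    if (length(plan$influxIdx))
        dC[plan$influxIdx] <- dC[plan$influxIdx] +
            theta[plan$nRxPar + seq_along(plan$influxIdx)]
    dC
}

ssRatioOf <- function(plan, C, theta, eps = 1e-12)
    max(abs(planRates(plan, C, theta)) / pmax(C, eps))

# damped Newton refinement toward dC/dt = 0; returns possibly improved state
newtonPolish <- function(plan, C, theta, tol = 1e-6, eps = 1e-12,
                         maxIter = 100L) {
    n <- plan$n
    for (iter in seq_len(maxIter)) {
        f <- planRates(plan, C, theta)
        if (max(abs(f) / pmax(C, eps)) < tol) return(C)
        J <- matrix(0, n, n)
        h <- pmax(abs(C), 1e-6) * 1e-7
        for (j in seq_len(n)) {
            Cp <- C; Cp[j] <- Cp[j] + h[j]
            Cm <- C; Cm[j] <- Cm[j] - h[j]
            J[, j] <- (planRates(plan, Cp, theta) -
                       planRates(plan, Cm, theta)) / (2 * h[j])
        }
        step <- tryCatch(-solve(J, f), error = function(e)
            -as.vector(MASS::ginv(J) %*% f))
        lam <- 1
        repeat {
            Cn <- C + lam * step
            if (all(Cn >= 0) &&
                sum(planRates(plan, Cn, theta)^2) < sum(f^2)) break
            lam <- lam / 2
            if (lam < 1e-8) return(C)   # no progress; keep integrated state
        }
        C <- Cn
    }
    C
}

integrateToSteadyState <- function(plan, C0, theta, tEnd, tol = 1e-6,
                                   eps = 1e-12, burnIn = 1) {
    deriv <- function(t, C, p) list(planRates(plan, C, theta))
    root <- function(t, C, p) {
        if (t < burnIn) return(1)
        ssRatioOf(plan, C, theta, eps) - tol
    }
    out <- deSolve::lsodar(y = C0, times = c(0, tEnd), func = deriv,
                           rootfunc = root, rtol = 1e-6, atol = 1e-9)
    as.numeric(out[nrow(out), 1 + seq_len(plan$n)])
}

#' Simulate steady-state concentration samples
#'
#' Draws samples from a kinetic model by perturbing every kinetic parameter
#' (rate constants, Vmax, Km, efflux and influx rates) independently and
#' uniformly within \eqn{\pm}\code{perturb} of its reference value, then
#' integrating the mass-balance ODE system from fixed initial
#' concentrations until the steady-state criterion
#' \eqn{\max_i |dC_i/dt| / \max(C_i, 10^{-12}) < 10^{-6}}
#' is met or \code{tEnd} simulated hours elapse. A state still drifting at
#' \code{tEnd} is refined by a damped Newton step toward the same fixed
#' point. Each sample's final concentration vector is one row of the
#' result.
#'
#' @param net a [MetabolicNetwork-class].
#' @param nSamples number of samples (rows) to generate.
#' @param perturb half-width of the relative parameter perturbation
#'   (default 0.10, i.e. \eqn{\pm 10\%}); \code{0} gives identical rows.
#' @param tEnd simulated hours to integrate at most (default 90).
#' @param seed integer seed; identical seeds give identical samples.
#' @param init optional named initial concentration vector. Default: 1.0
#'   everywhere, 10.0 at the core metabolite (the influx node, or the first
#'   node when the network has no influx).
#' @param ssTol steady-state criterion on the scaled derivative.
#' @return a [SampleMatrix-class] with attributes \code{ssRatio} (the
#'   realized criterion value per sample, re-evaluated from the rate
#'   equations at the returned state) and \code{paramFactors} (the realized
#'   perturbation multipliers, samples x parameters).
#' @examples
#' net <- generateNetwork(6, seed = 3)
#' sm <- simulateSamples(net, nSamples = 5, seed = 3)
#' sm
#' @export
simulateSamples <- function(net, nSamples, perturb = 0.10, tEnd = 90,
                            seed = 1L, init = NULL, ssTol = 1e-6) {
    stopifnot(is(net, "MetabolicNetwork"), nSamples >= 1, perturb >= 0)
    plan <- buildPlan(net)
    nPar <- length(plan$theta)
    if (is.null(init)) {
        init <- rep(1, plan$n)
        core <- if (length(plan$influxIdx)) plan$influxIdx[1] else 1L
        init[core] <- 10
    } else {
        stopifnot(length(init) == plan$n)
        init <- as.numeric(init[plan$nodes])
    }
    factors <- withSeed(seed, matrix(stats::runif(nSamples * nPar,
                                                  1 - perturb, 1 + perturb),
                                     nSamples, nPar, byrow = TRUE))
    vals <- matrix(NA_real_, nSamples, plan$n,
                   dimnames = list(NULL, plan$nodes))
    ratio <- numeric(nSamples)
    for (s in seq_len(nSamples)) {
        theta <- plan$theta * factors[s, ]
        C <- tryCatch(
            integrateToSteadyState(plan, init, theta, tEnd, tol = ssTol),
            error = function(e) stop("simulation failed for sample ", s,
                                     ": ", conditionMessage(e), call. = FALSE))
        if (any(C < -1e-9))
            stop("simulation failed for sample ", s,
                 ": negative concentration beyond tolerance", call. = FALSE)
        C <- pmax(C, 0)
        if (ssRatioOf(plan, C, theta) >= ssTol)
            C <- newtonPolish(plan, C, theta, tol = ssTol)
        vals[s, ] <- C
        ratio[s] <- ssRatioOf(plan, C, theta)
    }
    sm <- new("SampleMatrix", values = vals)
    attr(sm, "ssRatio") <- ratio
    attr(sm, "paramFactors") <- factors
    sm
}

#' Scaled steady-state residual of a concentration state
#'
#' Re-evaluates the mass-balance rate equations of \code{net} at a given
#' concentration vector and returns the steady-state criterion value
#' \eqn{\max_i |dC_i/dt| / \max(C_i, 10^{-12})}.
#'
#' @param net a [MetabolicNetwork-class].
#' @param conc named (or network-ordered) concentration vector.
#' @return numeric(1) scaled residual; values below \code{1e-6} indicate a
#'   state at steady state under the reference parameters.
#' @export
steadyStateResidual <- function(net, conc) {
    plan <- buildPlan(net)
    ssRatioOf(plan, as.numeric(conc), plan$theta)
}
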