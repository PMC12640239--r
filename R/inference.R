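# Network inference algorithms (NIAs): every method maps a SampleMatrix to
# a symmetric AssociationMatrix with zero diagonal.

sampleValues <- function(samples) {
    if (is(samples, "SampleMatrix")) as.matrix(samples) else as.matrix(samples)
}

# biweight midcorrelation of the columns of x (median/MAD biweight with the
# usual 9-MAD tuning constant); constant columns get weight-zero entries
bicorMatrix <- function(x) {
    n <- ncol(x)
    xt <- matrix(0, nrow(x), n)
    ok <- logical(n)
    for (j in seq_len(n)) {
        med <- stats::median(x[, j])
        mad <- stats::mad(x[, j], constant = 1)
        if (mad <= 0) next
        u <- (x[, j] - med) / (9 * mad)
        w <- (1 - u^2)^2 * (abs(u) < 1)
        xt[, j] <- (x[, j] - med) * w
        ok[j] <- sum(xt[, j]^2) > 0
    }
    denom <- sqrt(colSums(xt^2))
    r <- crossprod(xt) / outer(denom, denom)
    r[!ok, ] <- 0; r[, !ok] <- 0
    pmin(pmax(r, -1), 1)
}

#' Correlation-based association matrices
#'
#' Pairwise Pearson, Spearman, Kendall or biweight midcorrelation between
#' all metabolite columns. Constant columns yield zero association and a
#' message.
#'
#' @param samples a [SampleMatrix-class] (or samples-by-metabolites matrix).
#' @param method one of \code{"pearson"}, \code{"spearman"},
#'   \code{"kendall"}, \code{"bicor"}.
#' @return an [AssociationMatrix-class] of the \code{signed_correlation}
#'   family (entries in \eqn{[-1, 1]}, zero diagonal).
#' @examples
#' sm <- simulateSamples(generateNetwork(6, seed = 1), 30, seed = 1)
#' correlationAssociation(sm, "spearman")
#' @export
correlationAssociation <- function(samples,
        method = c("pearson", "spearman", "kendall", "bicor")) {
    method <- match.arg(method)
    x <- sampleValues(samples)
    if (nrow(x) < 3)
        stop("correlation requires at least 3 samples", call. = FALSE)
    const <- apply(x, 2, function(v) stats::sd(v) == 0)
    if (any(const))
        message("constant column(s) set to zero association: ",
                paste(colnames(x)[const], collapse = ", "))
    r <- if (method == "bicor") bicorMatrix(x)
         else suppressWarnings(stats::cor(x, method = method))
    r[is.na(r)] <- 0
    dimnames(r) <- list(colnames(x), colnames(x))
    newAssociation(r, "signed_correlation", method)
}

#' Partial correlation association matrix
#'
#' Full-order partial correlations from the (pseudo)inverse \eqn{P} of the
#' sample covariance: \eqn{pcor(i,j) = -P_{ij} / \sqrt{P_{ii} P_{jj}}}.
#' With fewer samples than metabolites the covariance is singular and the
#' Moore-Penrose pseudoinverse is used; an optional shrinkage flag blends
#' the covariance toward its diagonal first.
#'
#' @param samples a [SampleMatrix-class].
#' @param shrinkage optional shrinkage intensity in \eqn{[0, 1]} toward the
#'   diagonal of the covariance (default 0, no shrinkage).
#' @return an [AssociationMatrix-class], \code{signed_correlation} family.
#' @export
partialCorrelation <- function(samples, shrinkage = 0) {
    x <- sampleValues(samples)
    if (nrow(x) < 3)
        stop("partial correlation requires at least 3 samples", call. = FALSE)
    S <- stats::cov(x)
    if (shrinkage > 0)
        S <- (1 - shrinkage) * S + shrinkage * diag(diag(S))
    P <- MASS::ginv(S)
    d <- sqrt(abs(diag(P)))
    d[d == 0] <- 1
    pc <- -P / outer(d, d)
    pc <- (pc + t(pc)) / 2
    pc <- pmin(pmax(pc, -1), 1)
    dimnames(pc) <- list(colnames(x), colnames(x))
    newAssociation(pc, "signed_correlation", "pcor")
}

# Kraskov-Grassberger-Stoegbauer kNN mutual information (variant 1) for a
# single pair of columns, in nats
ksgPairMI <- function(x, y, k) {
    n <- length(x)
    dx <- abs(outer(x, x, "-"))
    dy <- abs(outer(y, y, "-"))
    dz <- pmax(dx, dy)
    diag(dz) <- Inf
    epsv <- apply(dz, 1, function(r) sort(r, partial = k)[k])
    nx <- rowSums(dx < epsv) - 1L   # excludes self
    ny <- rowSums(dy < epsv) - 1L
    digamma(k) + digamma(n) - mean(digamma(nx + 1) + digamma(ny + 1))
}

#' Mutual information association matrix (kNN estimator)
#'
#' Nonparametric mutual information between all metabolite pairs using the
#' Kraskov k-nearest-neighbour entropy estimator (variant 1), in nats.
#' A deterministic seeded jitter of magnitude \code{1e-10} standard
#' deviations breaks exact ties, which the kNN estimator cannot handle.
#' Negative estimates are clipped to zero; constant columns yield zero MI
#' with a message.
#'
#' @param samples a [SampleMatrix-class].
#' @param k number of nearest neighbours (default 3).
#' @param seed seed for the tie-breaking jitter.
#' @return an [AssociationMatrix-class], \code{nonnegative} family.
#' @export
mutualInformation <- function(samples, k = 3L, seed = 1L) {
    x <- sampleValues(samples)
    n <- nrow(x); p <- ncol(x)
    if (k < 1 || k >= n)
        stop("k must satisfy 1 <= k < number of samples", call. = FALSE)
    const <- apply(x, 2, function(v) stats::sd(v) == 0)
    if (any(const))
        message("constant column(s) given zero MI: ",
                paste(colnames(x)[const], collapse = ", "))
    x <- withSeed(seed, {
        sds <- apply(x, 2, stats::sd)
        sds[sds == 0] <- 1
        x + matrix(stats::rnorm(n * p), n, p) * rep(sds * 1e-10, each = n)
    })
    m <- matrix(0, p, p, dimnames = list(colnames(x), colnames(x)))
    for (i in seq_len(p - 1)) for (j in (i + 1):p) {
        if (const[i] || const[j]) next
        m[i, j] <- m[j, i] <- max(0, ksgPairMI(x[, i], x[, j], k))
    }
    newAssociation(m, "nonnegative", "mi")
}

#' Context likelihood of relatedness (CLR) transform
#'
#' Post-processes any association matrix by scoring each pair against the
#' background of its row and column: with row z-scores
#' \eqn{z_i = (a_{ij} - \mu_i)/\sigma_i} (diagonal excluded, negative
#' z-scores floored at zero), the output is
#' \eqn{\sqrt{\max(0, z_i)^2 + \max(0, z_j)^2}}. Signed inputs are
#' absolute-valued first. Zero-variance rows get z-scores of zero.
#'
#' @param assoc an [AssociationMatrix-class].
#' @return an [AssociationMatrix-class], \code{nonnegative} family.
#' @export
clrTransform <- function(assoc) {
    stopifnot(is(assoc, "AssociationMatrix"))
    a <- abs(as.matrix(assoc))
    n <- nrow(a)
    z <- matrix(0, n, n)
    for (i in seq_len(n)) {
        row <- a[i, -i]
        mu <- mean(row); sdv <- stats::sd(row)
        z[i, -i] <- if (is.na(sdv) || sdv == 0) 0 else (row - mu) / sdv
    }
    z <- pmax(z, 0)
    out <- sqrt(z^2 + t(z)^2)
    dimnames(out) <- dimnames(a)
    newAssociation(out, "nonnegative",
                   paste0("clr_", if (is.na(assoc@method)) "?" else assoc@method))
}

#' MRNET: maximum relevance / minimum redundancy network
#'
#' For every target variable, features are selected greedily by the MRMR
#' difference criterion: relevance (association with the target) minus mean
#' redundancy (association with features already selected). Each feature's
#' pairwise score is its MRMR criterion value at selection time, floored at
#' zero; the final matrix takes the maximum of the two directed scores.
#'
#' @param assoc a nonnegative [AssociationMatrix-class] (typically mutual
#'   information).
#' @return an [AssociationMatrix-class], \code{nonnegative} family.
#' @export
mrnet <- function(assoc) {
    stopifnot(is(assoc, "AssociationMatrix"))
    a <- abs(as.matrix(assoc))
    n <- nrow(a)
    s <- matrix(0, n, n)   # s[f, t]: score of feature f for target t
    for (t in seq_len(n)) {
        cand <- setdiff(seq_len(n), t)
        sel <- integer(0)
        while (length(cand)) {
            crit <- vapply(cand, function(f) {
                red <- if (length(sel)) mean(a[f, sel]) else 0
                a[f, t] - red
            }, numeric(1))
            best <- which.max(crit)
            s[cand[best], t] <- max(0, crit[best])
            sel <- c(sel, cand[best])
            cand <- cand[-best]
        }
    }
    out <- pmax(s, t(s))
    dimnames(out) <- dimnames(a)
    newAssociation(out, "nonnegative", "mrnet")
}

#' Tree-ensemble importance association matrix
#'
#' Regression-tree variable selection in the GENIE3 style: each metabolite
#' is masked in turn and a seeded random-forest regression (square-root
#' predictor subsampling, unlimited depth) predicts it from the remaining
#' metabolites. Importance is the total impurity reduction attributed to
#' each predictor, normalized per target; the matrix is symmetrized by the
#' elementwise maximum of the two directed scores.
#'
#' @param samples a [SampleMatrix-class].
#' @param nTrees trees per target ensemble (default 100).
#' @param seed integer seed; fixed seeds give identical matrices.
#' @return an [AssociationMatrix-class], \code{nonnegative} family.
#' @export
treeImportance <- function(samples, nTrees = 100L, seed = 1L) {
    x <- sampleValues(samples)
    if (nrow(x) < 5)
        stop("tree importance requires at least 5 samples", call. = FALSE)
    p <- ncol(x)
    imp <- matrix(0, p, p, dimnames = list(colnames(x), colnames(x)))
    for (t in seq_len(p)) {
        df <- as.data.frame(x)
        names(df) <- paste0("V", seq_len(p))
        fit <- ranger::ranger(
            y = x[, t], x = df[, -t, drop = FALSE],
            num.trees = nTrees, mtry = max(1L, floor(sqrt(p - 1))),
            importance = "impurity", seed = seed + t, num.threads = 1)
        vi <- fit$variable.importance
        vi[vi < 0] <- 0
        tot <- sum(vi)
        if (tot > 0) imp[-t, t] <- vi / tot
    }
    out <- pmax(imp, t(imp))
    newAssociation(out, "nonnegative", "genie3")
}

#' PCLRC: probabilistic CLR by repeated subsampling
#'
#' Repeatedly subsamples the rows (without replacement), computes a base
#' association matrix, applies the CLR transform and marks the top fraction
#' of off-diagonal pairs; the output entry for each pair is the fraction of
#' iterations in which it was marked. Defaults follow the original
#' procedure: 75\% subsamples, top 30\% of interactions.
#'
#' @param samples a [SampleMatrix-class].
#' @param baseMethod base association: \code{"pearson"} (the correlation
#'   variant) or \code{"mi"}.
#' @param subsampleFraction fraction of rows drawn each iteration (without
#'   replacement), default 0.75.
#' @param topFraction fraction of off-diagonal pairs marked per iteration,
#'   default 0.30.
#' @param iterations number of resampling rounds (default 1000).
#' @param perNode mark the top fraction per node row instead of globally
#'   over all pairs (default \code{FALSE}: global).
#' @param seed integer seed.
#' @param miK kNN neighbour count when \code{baseMethod = "mi"}.
#' @return an [AssociationMatrix-class] of selection frequencies in
#'   \eqn{[0, 1]}, \code{nonnegative} family.
#' @export
pclrc <- function(samples, baseMethod = c("pearson", "mi"),
                  subsampleFraction = 0.75, topFraction = 0.30,
                  iterations = 1000L, perNode = FALSE, seed = 1L, miK = 3L) {
    baseMethod <- match.arg(baseMethod)
    stopifnot(subsampleFraction > 0, subsampleFraction <= 1,
              topFraction > 0, topFraction < 1, iterations >= 1)
    x <- sampleValues(samples)
    m <- nrow(x); p <- ncol(x)
    nSub <- ceiling(subsampleFraction * m)
    if (nSub < 3)
        stop("subsample size below 3 samples", call. = FALSE)
    if (baseMethod == "mi" && nSub <= miK)
        stop("subsample size must exceed the MI neighbour count",
             call. = FALSE)
    nPairs <- p * (p - 1) / 2
    nTop <- max(1L, round(topFraction * nPairs))
    counts <- matrix(0, p, p, dimnames = list(colnames(x), colnames(x)))
    withSeed(seed, {
        for (it in seq_len(iterations)) {
            idx <- if (nSub == m) seq_len(m) else sample.int(m, nSub)
            sub <- x[idx, , drop = FALSE]
            base <- if (baseMethod == "pearson")
                correlationAssociation(new("SampleMatrix", values = sub),
                                       "pearson")
            else mutualInformation(new("SampleMatrix", values = sub),
                                   k = miK, seed = seed)
            cl <- as.matrix(clrTransform(base))
            mark <- matrix(0, p, p)
            if (perNode) {
                kNode <- max(1L, round(topFraction * (p - 1)))
                for (i in seq_len(p)) {
                    ord <- order(cl[i, -i], decreasing = TRUE)[seq_len(kNode)]
                    js <- setdiff(seq_len(p), i)[ord]
                    mark[i, js] <- 1
                }
                mark <- pmax(mark, t(mark))
            } else {
                v <- cl[upper.tri(cl)]
                top <- order(v, decreasing = TRUE)[seq_len(nTop)]
                sel <- numeric(nPairs); sel[top] <- 1
                mark <- symmetricFromUpper(sel, p, colnames(x))
            }
            counts <- counts + mark
        }
    })
    newAssociation(counts / iterations, "nonnegative",
                   paste0("pclrc_", baseMethod))
}

#' Run a named network inference algorithm
#'
#' Registry front-end mapping a method identifier to its NIA, so grids and
#' bootstraps can be configured by name. Supported identifiers:
#' \code{pearson}, \code{spearman}, \code{kendall}, \code{bicor},
#' \code{pcor}, \code{mi}, \code{clrp} (Pearson + CLR), \code{clrmi}
#' (MI + CLR), \code{mrnet}, \code{genie3}, \code{pclrc} (Pearson-based)
#' and \code{pclrcmi}.
#'
#' @param samples a [SampleMatrix-class].
#' @param method method identifier (see Details).
#' @param seed seed forwarded to stochastic methods.
#' @param ... further arguments forwarded to the underlying NIA (e.g.
#'   \code{iterations} for the PCLRC variants, \code{nTrees} for
#'   \code{genie3}).
#' @return an [AssociationMatrix-class].
#' @export
inferAssociation <- function(samples, method, seed = 1L, ...) {
    switch(method,
        pearson = ,
        spearman = ,
        kendall = ,
        bicor = correlationAssociation(samples, method),
        pcor = partialCorrelation(samples, ...),
        mi = mutualInformation(samples, seed = seed, ...),
        clrp = clrTransform(correlationAssociation(samples, "pearson")),
        clrmi = clrTransform(mutualInformation(samples, seed = seed, ...)),
        mrnet = mrnet(mutualInformation(samples, seed = seed, ...)),
        genie3 = treeImportance(samples, seed = seed, ...),
        pclrc = pclrc(samples, baseMethod = "pearson", seed = seed, ...),
        pclrcmi = pclrc(samples, baseMethod = "mi", seed = seed, ...),
        stop("unknown inference method: ", method, call. = FALSE))
}

#' Minimum sample size required by a method
#'
#' Used by [runGrid()] to gate methods whose preconditions a small sample
#' size cannot meet (e.g. the MI estimator needs more samples than its kNN
#' neighbour count, and PCLRC variants only see a subsample of the rows).
#'
#' @param method method identifier as in [inferAssociation()].
#' @param miK kNN neighbour count used by MI-based methods.
#' @param subsampleFraction PCLRC subsample fraction.
#' @return integer minimum number of samples.
#' @export
methodMinSamples <- function(method, miK = 3L, subsampleFraction = 0.75) {
    base <- switch(method,
        genie3 = 5L,
        mi = , clrmi = , mrnet = as.integer(miK + 1L),
        pclrc = 3L,
        pclrcmi = as.integer(miK + 1L),
        3L)
    if (method %in% c("pclrc", "pclrcmi"))
        base <- as.integer(ceiling(base / subsampleFraction))
    base
}
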