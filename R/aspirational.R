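# Aspirational association matrices: uniform noise plus a controlled
# proportion of the ground-truth edges, used to calibrate how evaluation
# metrics respond to signal quality.

#' Aspirational association matrix at a given signal level
#'
#' Each unordered off-diagonal pair receives one \eqn{U[0, 1]} draw
#' (mirrored for exact symmetry) plus \code{signal} times the reference
#' adjacency entry: \eqn{Asp(x, y) = U[0, 1] + signal \cdot Adj(x, y)}.
#' Entries therefore lie in \eqn{[0, 1 + signal]}; at signal 1 every true
#' edge outranks every non-edge and all metrics attain their optimum.
#'
#' @param adj reference [AdjacencyMatrix-class].
#' @param signal signal level in \eqn{[0, 1]}.
#' @param seed integer seed.
#' @return an [AssociationMatrix-class], \code{nonnegative} family.
#' @export
aspirationalMatrix <- function(adj, signal, seed = 1L) {
    stopifnot(signal >= 0, signal <= 1)
    a <- as.matrix(adj)
    n <- nrow(a)
    nPairs <- n * (n - 1) / 2
    u <- withSeed(seed, stats::runif(nPairs))
    vals <- u + signal * upperTriValues(a)
    newAssociation(symmetricFromUpper(vals, n, rownames(a)),
                   "nonnegative", "aspirational")
}

#' Sweep evaluation metrics across aspirational signal levels
#'
#' For each signal level and repetition, generates an aspirational matrix
#' and evaluates the requested pairwise metrics (AUROC, AUPR and
#' F1/MCC/FDR at the F1-optimal threshold) and, after binarizing at that
#' threshold, the four centrality MAEs.
#'
#' @param adj reference [AdjacencyMatrix-class].
#' @param signalLevels numeric vector of levels in \eqn{[0, 1]}; default
#'   the fifty levels \eqn{0.02, 0.04, \ldots, 1}.
#' @param matricesPerLevel repetitions per level (default 100).
#' @param metrics which metric groups to compute: any of
#'   \code{"pairwise"}, \code{"centrality"}.
#' @param seed integer master seed; each (level, repetition) cell derives
#'   its own seed deterministically.
#' @return tidy data.frame with columns \code{signal}, \code{repetition},
#'   \code{metric}, \code{value}.
#' @seealso [summarizeSweep()] for per-level means and 95\% CIs.
#' @export
signalSweep <- function(adj, signalLevels = seq(0.02, 1, by = 0.02),
                        matricesPerLevel = 100L,
                        metrics = c("pairwise", "centrality"), seed = 1L) {
    stopifnot(all(signalLevels >= 0), all(signalLevels <= 1),
              matricesPerLevel >= 1)
    metrics <- match.arg(metrics, several.ok = TRUE)
    rows <- vector("list", length(signalLevels) * matricesPerLevel)
    k <- 0L
    for (s in signalLevels) for (rep in seq_len(matricesPerLevel)) {
        cellSeed <- hashSeed("aspirational", s, rep, seed)
        asp <- aspirationalMatrix(adj, s, seed = cellSeed)
        out <- NULL
        if ("pairwise" %in% metrics) out <- pairwiseMetrics(asp, adj)
        if ("centrality" %in% metrics) {
            net <- optimalThreshold(asp, adj, "F1")$network
            out <- rbind(out[, c("metric", "value")],
                         centralityMetrics(net, adj))
        } else out <- out[, c("metric", "value")]
        k <- k + 1L
        rows[[k]] <- data.frame(signal = s, repetition = rep, out)
    }
    do.call(rbind, rows)
}

#' Per-level summary of a signal sweep
#'
#' @param sweep result of [signalSweep()].
#' @return data.frame with one row per (signal, metric): \code{mean},
#'   \code{ciLow}, \code{ciHigh} (2.5th and 97.5th percentiles over
#'   repetitions).
#' @export
summarizeSweep <- function(sweep) {
    agg <- split(sweep, list(sweep$signal, sweep$metric), drop = TRUE)
    out <- do.call(rbind, lapply(agg, function(d) {
        ci <- ci95(d$value)
        data.frame(signal = d$signal[1], metric = d$metric[1],
                   mean = mean(d$value), ciLow = ci[1], ciHigh = ci[2])
    }))
    rownames(out) <- NULL
    out[order(out$metric, out$signal), ]
}
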