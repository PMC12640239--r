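# Node-centrality measures on binary networks and per-node comparison of
# inferred vs reference networks.

binaryGraph <- function(net) {
    m <- if (is(net, "BinaryNetwork") || is(net, "AdjacencyMatrix"))
        as.matrix(net) else net
    igraph::graph_from_adjacency_matrix(m, mode = "undirected")
}

#' Centrality measures of a binary network
#'
#' Four measures over the undirected network:
#' \describe{
#'   \item{degree}{node degree normalized by \eqn{N - 1} (switchable to
#'     \eqn{N}).}
#'   \item{betweenness}{unnormalized shortest-path betweenness: for every
#'     unordered pair \eqn{j \ne k} (endpoints excluded) the fraction of
#'     shortest \eqn{j}-\eqn{k} paths passing through the node; unreachable
#'     pairs contribute 0.}
#'   \item{closeness}{harmonic closeness: the mean of inverse shortest-path
#'     distances to all other nodes, with \eqn{1/\infty = 0}, so
#'     disconnected graphs need no special-casing.}
#'   \item{pagerank}{the undirected-PageRank fixed point
#'     \eqn{R_i = \alpha \sum_j Adj_{ij} R_j / deg(j) + (1 - \alpha)/N},
#'     solved by power iteration; mass from isolated (dangling) nodes is
#'     redistributed uniformly so the vector always sums to 1.}
#' }
#'
#' @param net a [BinaryNetwork-class] or [AdjacencyMatrix-class].
#' @param measure one of \code{"degree"}, \code{"betweenness"},
#'   \code{"closeness"}, \code{"pagerank"}.
#' @param alpha PageRank damping factor (default 0.85).
#' @param tol PageRank convergence tolerance on the L1 residual.
#' @param maxIter PageRank iteration cap; non-convergence is an error
#'   reporting the last residual.
#' @param degreeDenominator \code{"N-1"} (default) or \code{"N"}.
#' @return named numeric vector of per-node centrality values.
#' @examples
#' adj <- networkToAdjacency(generateNetwork(8, seed = 1))
#' centrality(adj, "pagerank")
#' @export
centrality <- function(net,
        measure = c("degree", "betweenness", "closeness", "pagerank"),
        alpha = 0.85, tol = 1e-10, maxIter = 1000L,
        degreeDenominator = c("N-1", "N")) {
    measure <- match.arg(measure)
    m <- as.matrix(net)
    n <- nrow(m)
    nms <- rownames(m)
    val <- switch(measure,
        degree = {
            denom <- if (match.arg(degreeDenominator) == "N-1") n - 1 else n
            colSums(m) / denom
        },
        betweenness = igraph::betweenness(binaryGraph(net), directed = FALSE),
        closeness = igraph::harmonic_centrality(binaryGraph(net),
                                                normalized = FALSE) / (n - 1),
        pagerank = pagerankPower(m, alpha, tol, maxIter))
    stats::setNames(as.numeric(val), nms)
}

# power iteration for undirected PageRank with uniform dangling-mass
# teleportation; errors on non-convergence, reporting the last residual
pagerankPower <- function(m, alpha, tol, maxIter) {
    n <- nrow(m)
    deg <- colSums(m)
    dangling <- deg == 0
    M <- m / rep(pmax(deg, 1), each = n)   # column-stochastic on non-dangling
    r <- rep(1 / n, n)
    for (it in seq_len(maxIter)) {
        rNew <- alpha * (M %*% r + sum(r[dangling]) / n) + (1 - alpha) / n
        res <- sum(abs(rNew - r))
        r <- as.numeric(rNew)
        if (res < tol) return(r / sum(r))
    }
    stop("PageRank failed to converge in ", maxIter,
         " iterations (last L1 residual ", signif(res, 3), ")",
         call. = FALSE)
}

#' Per-node centrality comparison of inferred vs reference networks
#'
#' Computes one centrality measure on both networks and reports per-node
#' residuals (inferred minus reference; positive means the inferred network
#' overestimates) and their mean absolute error.
#'
#' @param pred inferred [BinaryNetwork-class].
#' @param ref reference [AdjacencyMatrix-class] with matching names.
#' @param measure centrality measure, as in [centrality()].
#' @param ... further arguments passed to [centrality()].
#' @return list with \code{measure}, \code{mae} (numeric), and
#'   \code{residuals} (data.frame: node, reference, inferred, residual).
#' @export
centralityError <- function(pred, ref, measure, ...) {
    checkSameNames(pred, ref, "prediction and reference")
    cp <- centrality(pred, measure, ...)
    cr <- centrality(ref, measure, ...)
    resid <- cp - cr
    list(measure = measure, mae = mean(abs(resid)),
         residuals = data.frame(node = names(resid), reference = cr,
                                inferred = cp, residual = resid,
                                row.names = NULL))
}

#' All four centrality MAEs of an inferred network
#'
#' @param pred inferred [BinaryNetwork-class].
#' @param ref reference [AdjacencyMatrix-class].
#' @param ... passed to [centrality()].
#' @return data.frame with columns \code{metric} (e.g.
#'   \code{"MAE_pagerank"}) and \code{value}.
#' @export
centralityMetrics <- function(pred, ref, ...) {
    measures <- c("degree", "betweenness", "closeness", "pagerank")
    data.frame(
        metric = paste0("MAE_", measures),
        value = vapply(measures, function(m)
            centralityError(pred, ref, m, ...)$mae, numeric(1)),
        row.names = NULL)
}
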