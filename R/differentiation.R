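# Bootstrapped consensus networks per condition and cross-condition
# differential edges, with a split-half reliability check.

edgeList <- function(binMat) {
    idx <- which(upper.tri(binMat) & binMat == 1, arr.ind = TRUE)
    nms <- rownames(binMat)
    if (!nrow(idx))
        return(data.frame(nodeA = character(), nodeB = character()))
    data.frame(nodeA = nms[idx[, 1]], nodeB = nms[idx[, 2]])
}

reliableFromFrequencies <- function(freq, threshold) {
    rel <- (freq > threshold) + 0
    diag(rel) <- 0
    new("BinaryNetwork", entries = rel, threshold = NA_real_)
}

# binarize one bootstrap association matrix: F1-optimal threshold against a
# reference when available, else keep the top-k ranked pairs
bootstrapBinarize <- function(assoc, reference, topK) {
    if (!is.null(reference))
        return(optimalThreshold(assoc, reference, "F1")$network)
    a <- abs(as.matrix(assoc))
    v <- upperTriValues(a)
    sel <- numeric(length(v))
    sel[order(v, decreasing = TRUE)[seq_len(topK)]] <- 1
    new("BinaryNetwork",
        entries = symmetricFromUpper(sel, nrow(a), rownames(a)),
        threshold = NA_real_)
}

#' Bootstrapped consensus network of one condition
#'
#' Repeatedly resamples the sample pool with replacement, infers a network
#' with the configured NIA, binarizes it, and accumulates per-pair edge
#' frequencies; the reliable-edge network keeps pairs present in strictly
#' more than \code{reliabilityThreshold} of the bootstrap networks
#' (default: in more than 50 of 100).
#'
#' Binarization uses the per-bootstrap F1-optimal threshold when a
#' reference adjacency is supplied, otherwise a rank-based top-\eqn{k}
#' rule (\code{topK} edges; defaults to the reference edge count when a
#' reference is given). A bootstrap draw on which the NIA fails (e.g. a
#' constant column) is retried with a fresh draw; more than 10 consecutive
#' retries is an error.
#'
#' @param samples a [SampleMatrix-class]: the condition's sample pool.
#' @param nia method identifier as in [inferAssociation()] (default
#'   \code{"clrp"}: Pearson + CLR).
#' @param nBootstrap number of bootstrap networks (default 100).
#' @param bootstrapSize samples drawn with replacement per bootstrap
#'   (default 100).
#' @param reliabilityThreshold strict frequency bound for reliable edges
#'   (default 0.5).
#' @param reference optional [AdjacencyMatrix-class] enabling F1-optimal
#'   binarization.
#' @param topK edges kept per bootstrap when no reference is supplied.
#' @param keepNetworks retain the per-bootstrap [BinaryNetwork-class] list
#'   (default \code{TRUE}; needed for [splitHalfAgreement()] and
#'   [edgePresenceTrace()]).
#' @param seed integer seed; fixed seeds reproduce frequencies exactly.
#' @param ... forwarded to [inferAssociation()].
#' @return a [ConsensusNetwork-class].
#' @export
bootstrapConsensus <- function(samples, nia = "clrp", nBootstrap = 100L,
                               bootstrapSize = 100L,
                               reliabilityThreshold = 0.5,
                               reference = NULL, topK = NULL,
                               keepNetworks = TRUE, seed = 1L, ...) {
    stopifnot(nBootstrap >= 2, reliabilityThreshold > 0,
              reliabilityThreshold < 1)
    x <- as.matrix(samples)
    if (nrow(x) < 3) stop("sample pool must hold at least 3 samples",
                          call. = FALSE)
    if (is.null(reference) && is.null(topK))
        stop("supply either a reference adjacency or topK", call. = FALSE)
    p <- ncol(x)
    counts <- matrix(0, p, p, dimnames = list(colnames(x), colnames(x)))
    nets <- if (keepNetworks) vector("list", nBootstrap) else list()
    withSeed(seed, {
        for (b in seq_len(nBootstrap)) {
            net <- NULL
            for (try in seq_len(11L)) {
                idx <- sample.int(nrow(x), bootstrapSize, replace = TRUE)
                sub <- new("SampleMatrix",
                           values = x[idx, , drop = FALSE])
                net <- tryCatch({
                    assoc <- suppressMessages(
                        inferAssociation(sub, nia, seed = seed + b, ...))
                    bootstrapBinarize(assoc, reference, topK)
                }, error = function(e) NULL)
                if (!is.null(net)) break
                message("bootstrap ", b, ": inference failed, retrying")
            }
            if (is.null(net))
                stop("bootstrap ", b, " failed after 10 retries",
                     call. = FALSE)
            counts <- counts + as.matrix(net)
            if (keepNetworks) nets[[b]] <- net
        }
    })
    freq <- counts / nBootstrap
    new("ConsensusNetwork", frequencies = freq,
        reliable = reliableFromFrequencies(freq, reliabilityThreshold),
        reliabilityThreshold = reliabilityThreshold, networks = nets)
}

#' Differential edges between two consensus networks
#'
#' Splits the symmetric difference of the two reliable edge sets by side:
#' edges reliable only in \code{a}, and edges reliable only in \code{b}.
#'
#' @param a,b [ConsensusNetwork-class] objects over the same metabolites.
#' @return list with data.frames \code{onlyA}, \code{onlyB} (columns
#'   \code{nodeA}, \code{nodeB}) and \code{nDisagreement}, the total count
#'   of edges in disagreement.
#' @export
differentialEdges <- function(a, b) {
    checkSameNames(a, b, "consensus networks")
    ma <- as.matrix(reliableNetwork(a))
    mb <- as.matrix(reliableNetwork(b))
    list(onlyA = edgeList((ma == 1 & mb == 0) + 0),
         onlyB = edgeList((mb == 1 & ma == 0) + 0),
         nDisagreement = sum((ma != mb)[upper.tri(ma)]))
}

#' Split-half reliability check of a bootstrap run
#'
#' Partitions the per-bootstrap networks into two halves (first/second by
#' index; odd counts give the larger first half), builds each half's
#' reliable-edge set at the same strict threshold, and counts agreements
#' and disagreements between the halves.
#'
#' @param networks list of per-bootstrap [BinaryNetwork-class] (e.g. from a
#'   [ConsensusNetwork-class] built with \code{keepNetworks = TRUE}).
#' @param reliabilityThreshold strict frequency bound (default 0.5).
#' @return list with \code{onlyFirst}, \code{onlySecond} (edge counts
#'   unique to each half's reliable set), \code{nDisagreement} (their sum)
#'   and \code{nAgreement} (edges reliable in both halves).
#' @export
splitHalfAgreement <- function(networks, reliabilityThreshold = 0.5) {
    nb <- length(networks)
    if (nb < 4) stop("need at least 4 bootstrap networks", call. = FALSE)
    if (nb %% 2 == 1) message("odd network count: first half is larger")
    half <- ceiling(nb / 2)
    freqOf <- function(nets)
        Reduce(`+`, lapply(nets, as.matrix)) / length(nets)
    r1 <- as.matrix(reliableFromFrequencies(freqOf(networks[seq_len(half)]),
                                            reliabilityThreshold))
    r2 <- as.matrix(reliableFromFrequencies(
        freqOf(networks[(half + 1):nb]), reliabilityThreshold))
    ut <- upper.tri(r1)
    list(onlyFirst = sum((r1 == 1 & r2 == 0)[ut]),
         onlySecond = sum((r2 == 1 & r1 == 0)[ut]),
         nDisagreement = sum((r1 != r2)[ut]),
         nAgreement = sum((r1 == 1 & r2 == 1)[ut]))
}

#' Count bootstrap networks containing a given edge
#'
#' @param networks list of per-bootstrap [BinaryNetwork-class].
#' @param edge character(2): the two metabolite names.
#' @return integer count; divided by the bootstrap count it equals the
#'   consensus frequency entry for the pair.
#' @export
edgePresenceTrace <- function(networks, edge) {
    stopifnot(length(edge) == 2)
    nms <- nodeNames(networks[[1]])
    if (!all(edge %in% nms))
        stop("unknown node name(s): ",
             paste(setdiff(edge, nms), collapse = ", "), call. = FALSE)
    sum(vapply(networks, function(n) as.matrix(n)[edge[1], edge[2]],
               numeric(1)))
}
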