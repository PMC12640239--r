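# Edge-level scoring of an association matrix against a reference
# adjacency. All counting is over the n(n-1)/2 unordered off-diagonal
# pairs (undirected evaluation).

#' Threshold an association matrix into a binary network
#'
#' An edge is present when \eqn{|A(x, y)| > \tau} (strict inequality);
#' signed matrices are absolute-valued.
#'
#' @param assoc an [AssociationMatrix-class].
#' @param tau threshold.
#' @return a [BinaryNetwork-class] recording the threshold used.
#' @export
binarize <- function(assoc, tau) {
    a <- abs(as.matrix(assoc))
    b <- (a > tau) + 0
    diag(b) <- 0
    new("BinaryNetwork", entries = b, threshold = as.numeric(tau))
}

#' Confusion counts over unordered metabolite pairs
#'
#' @param pred a [BinaryNetwork-class].
#' @param ref an [AdjacencyMatrix-class] with the same name order.
#' @return named list with integers \code{TP}, \code{FP}, \code{FN},
#'   \code{TN}; the four sum to \eqn{n(n-1)/2}.
#' @export
confusion <- function(pred, ref) {
    checkSameNames(pred, ref, "prediction and reference")
    p <- upperTriValues(as.matrix(pred))
    r <- upperTriValues(as.matrix(ref))
    list(TP = sum(p == 1 & r == 1), FP = sum(p == 1 & r == 0),
         FN = sum(p == 0 & r == 1), TN = sum(p == 0 & r == 0))
}

#' F1 score, Matthews correlation and false discovery rate
#'
#' \code{f1}: harmonic mean of precision and recall,
#' \eqn{2TP / (2TP + FP + FN)}. \code{mcc}: the Matthews correlation
#' coefficient. \code{fdr}: \eqn{FP / (TP + FP)}. Degenerate denominators
#' return 0 (no predictions mean no false discoveries; an all-zero MCC
#' denominator factor gives 0).
#'
#' @param c confusion counts as returned by [confusion()].
#' @return numeric(1).
#' @export
f1 <- function(c) {
    d <- 2 * c$TP + c$FP + c$FN
    if (d == 0) 0 else 2 * c$TP / d
}

#' @rdname f1
#' @export
mcc <- function(c) {
    d <- (c$TP + c$FP) * (c$TP + c$FN) * (c$TN + c$FP) * (c$TN + c$FN)
    if (d == 0) return(0)
    (c$TP * c$TN - c$FP * c$FN) / sqrt(d)
}

#' @rdname f1
#' @export
fdr <- function(c) {
    d <- c$TP + c$FP
    if (d == 0) 0 else c$FP / d
}

#' Criterion-optimal binarization threshold
#'
#' Scans candidate thresholds (midpoints between consecutive sorted unique
#' absolute association values, plus one below the minimum and one above
#' the maximum) and returns the threshold maximizing F1 or MCC against the
#' reference; ties resolve to the smallest threshold.
#'
#' @param assoc an [AssociationMatrix-class].
#' @param ref an [AdjacencyMatrix-class] with matching names.
#' @param criterion \code{"F1"} or \code{"MCC"}.
#' @return list with \code{tau} (numeric), \code{value} (criterion at
#'   \code{tau}) and \code{network} (the [BinaryNetwork-class] at
#'   \code{tau}).
#' @export
optimalThreshold <- function(assoc, ref, criterion = c("F1", "MCC")) {
    criterion <- match.arg(criterion)
    checkSameNames(assoc, ref, "association and reference")
    v <- sort(unique(upperTriValues(abs(as.matrix(assoc)))))
    cand <- c(v[1] - 1,
              if (length(v) > 1) (v[-1] + v[-length(v)]) / 2,
              v[length(v)] + 1)
    score <- if (criterion == "F1") f1 else mcc
    best <- -Inf; bestTau <- cand[1]; bestNet <- NULL
    for (tau in cand) {
        net <- binarize(assoc, tau)
        s <- score(confusion(net, ref))
        if (s > best + 1e-12) {
            best <- s; bestTau <- tau; bestNet <- net
        }
    }
    list(tau = bestTau, value = best, network = bestNet)
}

#' Areas under the ROC and precision-recall curves
#'
#' \code{auroc} scores the ranking of true edges above non-edges by
#' absolute association (the Mann-Whitney rank statistic; tied scores get
#' averaged ranks). \code{aupr} sums the non-interpolated (step-wise)
#' precision-recall curve, grouping tied scores.
#'
#' @param assoc an [AssociationMatrix-class].
#' @param ref an [AdjacencyMatrix-class] with at least one edge and one
#'   non-edge.
#' @return numeric(1) in \eqn{[0, 1]}.
#' @export
auroc <- function(assoc, ref) {
    checkSameNames(assoc, ref, "association and reference")
    s <- upperTriValues(abs(as.matrix(assoc)))
    y <- upperTriValues(as.matrix(ref))
    P <- sum(y == 1); N <- sum(y == 0)
    if (P == 0 || N == 0)
        stop("reference must contain at least one edge and one non-edge",
             call. = FALSE)
    rk <- rank(s)
    (sum(rk[y == 1]) - P * (P + 1) / 2) / (P * N)
}

#' @rdname auroc
#' @export
aupr <- function(assoc, ref) {
    checkSameNames(assoc, ref, "association and reference")
    s <- upperTriValues(abs(as.matrix(assoc)))
    y <- upperTriValues(as.matrix(ref))
    P <- sum(y == 1)
    if (P == 0 || sum(y == 0) == 0)
        stop("reference must contain at least one edge and one non-edge",
             call. = FALSE)
    ord <- order(s, decreasing = TRUE)
    s <- s[ord]; y <- y[ord]
    ## group tied scores into blocks; step-wise (non-interpolated) summation
    blocks <- cumsum(!duplicated(s))
    tpBlock <- tapply(y, blocks, sum)
    nBlock <- tapply(y, blocks, length)
    tp <- cumsum(tpBlock)
    npred <- cumsum(nBlock)
    prec <- tp / npred
    recall <- tp / P
    sum(diff(c(0, recall)) * prec)
}

#' Evaluate all pairwise metrics of an association matrix
#'
#' Computes AUROC, AUPR and, at the F1-optimal threshold, F1, MCC and FDR
#' against the reference adjacency.
#'
#' @param assoc an [AssociationMatrix-class].
#' @param ref an [AdjacencyMatrix-class].
#' @return data.frame with columns \code{metric}, \code{value},
#'   \code{threshold} (\code{NA} for threshold-free metrics).
#' @export
pairwiseMetrics <- function(assoc, ref) {
    opt <- optimalThreshold(assoc, ref, "F1")
    cc <- confusion(opt$network, ref)
    data.frame(
        metric = c("AUROC", "AUPR", "F1", "MCC", "FDR"),
        value = c(auroc(assoc, ref), aupr(assoc, ref),
                  f1(cc), mcc(cc), fdr(cc)),
        threshold = c(NA, NA, opt$tau, opt$tau, opt$tau))
}
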