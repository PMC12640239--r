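# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# all-pairs shortest-path distances by repeated BFS on a binary adjacency
bfsDistances <- function(m) {
    n <- nrow(m)
    d <- matrix(Inf, n, n)
    for (s in seq_len(n)) {
        d[s, s] <- 0
        frontier <- s
        lvl <- 0
        while (length(frontier)) {
            lvl <- lvl + 1
            nxt <- integer(0)
            for (v in frontier)
                nxt <- c(nxt, which(m[v, ] == 1 & is.infinite(d[s, ])))
            nxt <- setdiff(unique(nxt), which(!is.infinite(d[s, ])))
            d[s, nxt] <- lvl
            frontier <- nxt
        }
    }
    d
}

# number of shortest paths between every pair, by DP over BFS levels
shortestPathCounts <- function(m, d) {
    n <- nrow(m)
    cnt <- matrix(0, n, n)
    for (s in seq_len(n)) {
        cnt[s, s] <- 1
        for (lvl in sort(unique(d[s, is.finite(d[s, ]) & d[s, ] > 0]))) {
            for (v in which(d[s, ] == lvl)) {
                preds <- which(m[v, ] == 1 & d[s, ] == lvl - 1)
                cnt[s, v] <- sum(cnt[s, preds])
            }
        }
    }
    cnt
}

# Eq.-style betweenness: unordered pairs, endpoints excluded, unreachable
# pairs contribute nothing
oracleBetweenness <- function(m) {
    n <- nrow(m)
    d <- bfsDistances(m)
    cnt <- shortestPathCounts(m, d)
    bc <- numeric(n)
    for (i in seq_len(n)) for (j in seq_len(n - 1)) for (k in (j + 1):n) {
        if (i == j || i == k || is.infinite(d[j, k])) next
        if (is.finite(d[j, i]) && is.finite(d[i, k]) &&
            d[j, i] + d[i, k] == d[j, k])
            bc[i] <- bc[i] + cnt[j, i] * cnt[i, k] / cnt[j, k]
    }
    bc
}

oracleCloseness <- function(m) {
    d <- bfsDistances(m)
    n <- nrow(m)
    vapply(seq_len(n), function(i) sum(1 / d[i, -i]) / (n - 1), numeric(1))
}

# dense linear solve of the PageRank fixed point with uniform dangling
# teleportation
oraclePagerank <- function(m, alpha = 0.85) {
    m <- unname(m)
    n <- nrow(m)
    deg <- colSums(m)
    M <- m / rep(pmax(deg, 1), each = n)
    dang <- as.numeric(deg == 0)
    A <- diag(n) - alpha * M - alpha * outer(rep(1 / n, n), dang)
    r <- solve(A, rep((1 - alpha) / n, n))
    r / sum(r)
}

# greedy MRMR recursion written independently (recursive form)
oracleMrmr <- function(a) {
    n <- nrow(a)
    s <- matrix(0, n, n)
    for (t in seq_len(n)) {
        recurse <- function(sel, cand) {
            if (!length(cand)) return()
            vals <- sapply(cand, function(f)
                a[f, t] - (if (length(sel)) sum(a[f, sel]) / length(sel)
                           else 0))
            f <- cand[which.max(vals)]
            s[f, t] <<- max(0, max(vals))
            recurse(c(sel, f), setdiff(cand, f))
        }
        recurse(integer(0), setdiff(seq_len(n), t))
    }
    pmax(s, t(s))
}

# two-loop CLR z-score oracle
oracleClr <- function(a) {
    a <- abs(a)
    n <- nrow(a)
    out <- matrix(0, n, n)
    zed <- function(i, j) {
        row <- a[i, -i]
        if (sd(row) == 0) return(0)
        max(0, (a[i, j] - mean(row)) / sd(row))
    }
    for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
        out[i, j] <- sqrt(zed(i, j)^2 + zed(j, i)^2)
    out
}

# AUROC by explicit pair counting (ties count one half)
oracleAuroc <- function(scores, labels) {
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    tot <- 0
    for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
    tot / (length(pos) * length(neg))
}

# exhaustive optimal-threshold scan by direct confusion counting
oracleOptimalF1 <- function(a, refm) {
    s <- abs(a[upper.tri(a)])
    y <- refm[upper.tri(refm)]
    v <- sort(unique(s))
    cands <- c(v[1] - 1, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2,
               v[length(v)] + 1)
    f1At <- function(tau) {
        pred <- s > tau
        tp <- sum(pred & y == 1); fp <- sum(pred & y == 0)
        fn <- sum(!pred & y == 1)
        if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    }
    vals <- vapply(cands, f1At, numeric(1))
    list(tau = cands[which.max(vals)], value = max(vals))
}

# small fixtures ------------------------------------------------------------

adjFromEdges <- function(n, edges, nms = sprintf("M%02d", seq_len(n))) {
    m <- matrix(0, n, n, dimnames = list(nms, nms))
    for (e in edges) { m[e[1], e[2]] <- 1; m[e[2], e[1]] <- 1 }
    new("AdjacencyMatrix", adj = m)
}

binFromEdges <- function(n, edges, nms = sprintf("M%02d", seq_len(n))) {
    m <- as.matrix(adjFromEdges(n, edges, nms))
    new("BinaryNetwork", entries = m, threshold = NA_real_)
}

assocFromUpper <- function(vals, n, family = "nonnegative",
                           nms = sprintf("M%02d", seq_len(n))) {
    m <- matrix(0, n, n, dimnames = list(nms, nms))
    m[upper.tri(m)] <- vals
    m <- m + t(m)
    new("AssociationMatrix", entries = m, family = family)
}

sampleMat <- function(m) {
    if (is.null(colnames(m)))
        colnames(m) <- sprintf("M%02d", seq_len(ncol(m)))
    new("SampleMatrix", values = m)
}

randomBinaryNet <- function(n, p = 0.4) {
    v <- as.numeric(runif(n * (n - 1) / 2) < p)
    nms <- sprintf("M%02d", seq_len(n))
    m <- matrix(0, n, n, dimnames = list(nms, nms))
    m[upper.tri(m)] <- v
    m <- m + t(m)
    new("BinaryNetwork", entries = m, threshold = NA_real_)
}
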