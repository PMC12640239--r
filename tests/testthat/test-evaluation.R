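test_that("binarization uses a strict threshold", {
    a <- assocFromUpper(c(0.2, 0.7, 0.4), 3)
    expect_equal(sum(as.matrix(binarize(a, 0.6))) / 2, 1)
    expect_equal(sum(as.matrix(binarize(a, 0.7))), 0)     # strict >
    expect_equal(sum(as.matrix(binarize(a, 0.1))) / 2, 3)
    # signed matrices binarize on absolute value
    s <- assocFromUpper(c(-0.9, 0.1, 0.2), 3, family = "signed_correlation")
    expect_equal(sum(as.matrix(binarize(s, 0.6))) / 2, 1)
})

test_that("confusion counts enumerate unordered pairs", {
    ref <- adjFromEdges(4, list(c(1, 2), c(2, 3), c(3, 4)))
    predEq <- binFromEdges(4, list(c(1, 2), c(2, 3), c(3, 4)))
    cc <- confusion(predEq, ref)
    expect_equal(cc, list(TP = 3L, FP = 0L, FN = 0L, TN = 3L))
    # complement: no pair classified correctly as edge or non-edge
    comp <- binFromEdges(4, list(c(1, 3), c(1, 4), c(2, 4)))
    cc2 <- confusion(comp, ref)
    expect_equal(cc2$TP, 0L); expect_equal(cc2$TN, 0L)
    # 4-node toy enumerated by hand over all 6 pairs
    pred <- binFromEdges(4, list(c(1, 2), c(1, 3)))
    cc3 <- confusion(pred, ref)
    expect_equal(cc3, list(TP = 1L, FP = 1L, FN = 2L, TN = 2L))
    expect_equal(cc3$TP + cc3$FP + cc3$FN + cc3$TN, 6L)
    badRef <- adjFromEdges(4, list(c(1, 2)), nms = letters[1:4])
    expect_error(confusion(pred, badRef), "mismatched")
})

test_that("F1, MCC and FDR follow their defining arithmetic", {
    expect_equal(f1(list(TP = 2, FP = 1, FN = 1, TN = 0)), 4 / 6)
    expect_equal(mcc(list(TP = 3, FP = 0, FN = 0, TN = 3)), 1)
    expect_equal(mcc(list(TP = 0, FP = 3, FN = 3, TN = 0)), -1)
    expect_equal(mcc(list(TP = 1, FP = 1, FN = 1, TN = 1)), 0)
    expect_equal(fdr(list(TP = 1, FP = 3, FN = 0, TN = 2)), 0.75)
    # degenerate denominators return defined values
    expect_equal(f1(list(TP = 0, FP = 0, FN = 0, TN = 6)), 0)
    expect_equal(mcc(list(TP = 0, FP = 0, FN = 3, TN = 3)), 0)
    expect_equal(fdr(list(TP = 0, FP = 0, FN = 3, TN = 3)), 0)
    # FDR + precision = 1 whenever predictions exist
    cc <- list(TP = 4, FP = 3, FN = 2, TN = 1)
    expect_equal(fdr(cc) + cc$TP / (cc$TP + cc$FP), 1)
})

test_that("optimal threshold matches the exhaustive scan oracle", {
    ref <- adjFromEdges(4, list(c(1, 2), c(2, 3), c(3, 4)))
    # noiseless 0/1 association: criterion 1, smallest candidate returned
    perfect <- assocFromUpper(as.matrix(ref)[upper.tri(as.matrix(ref))], 4)
    opt <- optimalThreshold(perfect, ref, "F1")
    expect_equal(opt$value, 1)
    expect_equal(opt$tau, 0.5)   # smallest tau attaining the maximum
    set.seed(13)
    for (i in 1:10) {
        a <- assocFromUpper(runif(6), 4)
        got <- optimalThreshold(a, ref, "F1")
        want <- oracleOptimalF1(as.matrix(a), as.matrix(ref))
        expect_equal(got$value, want$value)
        expect_equal(got$tau, want$tau)
        # maximality against random threshold probes
        for (tau in runif(5))
            expect_gte(got$value + 1e-12,
                       f1(confusion(binarize(a, tau), ref)))
    }
    mccOpt <- optimalThreshold(a, ref, "MCC")
    for (tau in runif(5))
        expect_gte(mccOpt$value + 1e-12,
                   mcc(confusion(binarize(a, tau), ref)))
})

test_that("AUROC and AUPR honor their tie and extreme conventions", {
    ref <- adjFromEdges(4, list(c(1, 2), c(2, 3), c(3, 4)))
    y <- as.matrix(ref)[upper.tri(as.matrix(ref))]
    # perfect ranking
    perfect <- assocFromUpper(ifelse(y == 1, 0.9, 0.1), 4)
    expect_equal(auroc(perfect, ref), 1)
    expect_equal(aupr(perfect, ref), 1)
    # all scores equal: AUROC 0.5, AUPR = prevalence
    flat <- assocFromUpper(rep(0.5, 6), 4)
    expect_equal(auroc(flat, ref), 0.5)
    expect_equal(aupr(flat, ref), 0.5)
    # AUROC invariant under strictly increasing transforms
    set.seed(17)
    a <- assocFromUpper(runif(6), 4)
    a2 <- assocFromUpper(sqrt(as.matrix(a)[upper.tri(as.matrix(a))]), 4)
    expect_equal(auroc(a, ref), auroc(a2, ref))
    # degenerate reference is an error
    empty <- adjFromEdges(4, list())
    expect_error(auroc(a, empty), "at least one edge")
})

test_that("random scores give null AUROC near one half", {
    set.seed(19)
    refAdj <- adjFromEdges(20, lapply(1:19, function(i) c(i, i + 1)))
    vals <- replicate(100, {
        a <- assocFromUpper(runif(190), 20)
        auroc(a, refAdj)
    })
    expect_lt(abs(mean(vals) - 0.5), 0.05)
})
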