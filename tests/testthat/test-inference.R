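test_that("correlation families behave on canonical examples", {
    x <- c(1, 2, 3); y <- c(2, 4, 6)
    sm <- sampleMat(cbind(A = x, B = y))
    for (m in c("pearson", "spearman", "kendall"))
        expect_equal(as.matrix(correlationAssociation(sm, m))["A", "B"], 1)

    # monotone but nonlinear: rank methods saturate, Pearson does not
    sm2 <- sampleMat(cbind(A = c(1, 2, 3), B = c(1, 4, 9)))
    expect_equal(as.matrix(correlationAssociation(sm2, "spearman"))["A", "B"], 1)
    expect_lt(as.matrix(correlationAssociation(sm2, "pearson"))["A", "B"], 1)

    # bicor agrees with pearson on clean Gaussian data
    set.seed(7)
    n <- 200
    a <- rnorm(n); b <- 0.8 * a + sqrt(1 - 0.64) * rnorm(n)
    sm3 <- sampleMat(cbind(A = a + 10, B = b + 10))
    bc <- as.matrix(correlationAssociation(sm3, "bicor"))["A", "B"]
    pe <- as.matrix(correlationAssociation(sm3, "pearson"))["A", "B"]
    expect_lt(abs(bc - pe), 0.1)

    expect_error(correlationAssociation(sampleMat(cbind(A = 1:2, B = 2:3))),
                 "3 samples")
    expect_message(correlationAssociation(
        sampleMat(cbind(A = c(1, 1, 1), B = c(1, 2, 3))), "pearson"),
        "constant")
})

test_that("partial correlation exposes the collider and matches residual cor", {
    set.seed(3)
    n <- 400
    x <- rnorm(n); y <- rnorm(n)
    z <- x + y + rnorm(n, sd = 0.05)
    sm <- sampleMat(cbind(X = x + 20, Y = y + 20, Z = z + 40))
    pc <- as.matrix(partialCorrelation(sm))
    expect_lt(pc["X", "Y"], -0.9)
    expect_lt(abs(cor(x, y)), 0.15)
    # brute-force oracle: correlation of regression residuals
    rx <- resid(lm(x ~ z)); ry <- resid(lm(y ~ z))
    expect_equal(pc["X", "Y"], cor(rx, ry), tolerance = 1e-6)

    # jointly independent columns stay near zero
    set.seed(11)
    ind <- sampleMat(matrix(runif(500 * 4), 500, 4))
    pci <- as.matrix(partialCorrelation(ind))
    expect_lt(max(abs(pci[upper.tri(pci)])), 0.2)

    # singular covariance (n <= p) is handled, never a crash
    set.seed(2)
    wide <- sampleMat(matrix(runif(5 * 8), 5, 8))
    expect_s4_class(partialCorrelation(wide), "AssociationMatrix")
})

test_that("kNN mutual information tracks the Gaussian closed form", {
    set.seed(5)
    n <- 500
    sm <- sampleMat(cbind(A = runif(n), B = runif(n)))
    expect_lt(as.matrix(mutualInformation(sm, seed = 1))["A", "B"], 0.05)

    rho <- 0.9; n2 <- 2000
    set.seed(6)
    a <- rnorm(n2); b <- rho * a + sqrt(1 - rho^2) * rnorm(n2)
    sm2 <- sampleMat(cbind(A = a + 10, B = b + 10))
    est <- as.matrix(mutualInformation(sm2, seed = 1))["A", "B"]
    expect_lt(abs(est - (-0.5 * log(1 - rho^2))), 0.1)

    # diagonal zeroed, output symmetric nonnegative, deterministic
    m <- as.matrix(mutualInformation(sm, seed = 2))
    expect_true(all(diag(m) == 0) && all(m >= 0))
    expect_identical(m, t(m))
    expect_identical(m, as.matrix(mutualInformation(sm, seed = 2)))
})

test_that("CLR matches the two-loop z-score oracle", {
    # all off-diagonal entries equal: every z-score is 0
    flat <- assocFromUpper(rep(0.4, 6), 4)
    expect_true(all(as.matrix(clrTransform(flat)) == 0))

    # 3x3 toy: the strong pair ranks first
    toy <- assocFromUpper(c(0.9, 0.1, 0.1), 3)
    ct <- as.matrix(clrTransform(toy))
    expect_equal(which.max(ct[upper.tri(ct)]), 1L)

    set.seed(9)
    for (i in 1:5) {
        n <- sample(4:7, 1)
        a <- assocFromUpper(runif(n * (n - 1) / 2), n)
        got <- unname(as.matrix(clrTransform(a)))
        expect_equal(got, oracleClr(as.matrix(a)), tolerance = 1e-12)
        expect_true(all(got >= 0))
        expect_equal(got, t(got))
    }
})

test_that("MRNET equals the exhaustive MRMR recursion at small n", {
    set.seed(4)
    for (n in c(3, 4)) for (i in 1:10) {
        a <- assocFromUpper(runif(n * (n - 1) / 2), n)
        got <- unname(as.matrix(mrnet(a)))
        expect_equal(got, oracleMrmr(as.matrix(a)), tolerance = 1e-12)
    }
    # first-selected feature per target is the argmax-relevance feature:
    # the top-relevance pair keeps its raw relevance as its score
    a <- assocFromUpper(c(0.8, 0.3, 0.6), 3)
    m <- as.matrix(mrnet(a))
    expect_equal(m[1, 2], 0.8)
    expect_identical(m, t(m))
})

test_that("tree importance recovers a planted signal and is symmetric", {
    set.seed(8)
    n <- 200
    x <- matrix(runif(n * 5, 1, 2), n, 5)
    x[, 2] <- 2 * x[, 1] + rnorm(n, sd = 0.01)
    sm <- sampleMat(x)
    ti <- as.matrix(treeImportance(sm, seed = 5))
    # predictor 1 dominates target 2
    expect_equal(unname(which.max(ti[-2, 2])), 1L)
    expect_identical(ti, t(ti))
    expect_identical(ti, as.matrix(treeImportance(sm, seed = 5)))
    expect_error(treeImportance(sampleMat(x[1:4, ])), "5 samples")
})

test_that("PCLRC frequencies follow the marking mechanism", {
    net <- generateNetwork(5, 0, 0.5, seed = 21)
    sm <- simulateSamples(net, 20, seed = 21)
    # degenerate resampling: every iteration identical, exactly the top
    # fraction of the 10 pairs (3) marked every time
    p1 <- as.matrix(pclrc(sm, subsampleFraction = 1, iterations = 20,
                          seed = 2))
    v <- p1[upper.tri(p1)]
    expect_true(all(v %in% c(0, 1)))
    expect_equal(sum(v), 3)
    # frequencies bounded and reproducible
    p2 <- pclrc(sm, iterations = 30, seed = 3)
    m2 <- as.matrix(p2)
    expect_true(all(m2 >= 0 & m2 <= 1))
    expect_identical(m2, as.matrix(pclrc(sm, iterations = 30, seed = 3)))
    # each iteration marks exactly the top fraction, so the mean frequency
    # equals it up to rounding of the per-iteration count
    expect_equal(mean(m2[upper.tri(m2)]), 0.3, tolerance = 1e-12)
    expect_error(pclrc(sampleMat(matrix(runif(9), 3, 3)),
                       subsampleFraction = 0.5), "below 3")
})

test_that("rank-based methods are invariant under monotone transforms", {
    net <- generateNetwork(6, 1, 0.5, seed = 31)
    sm <- simulateSamples(net, 25, seed = 31)
    x <- as.matrix(sm)
    xt <- x; xt[, 2] <- exp(xt[, 2]); xt[, 5] <- xt[, 5]^3
    for (m in c("spearman", "kendall"))
        expect_equal(as.matrix(correlationAssociation(sampleMat(x), m)),
                     as.matrix(correlationAssociation(sampleMat(xt), m)),
                     tolerance = 1e-12)
})

test_that("deterministic NIAs are equivariant to sample-row permutation", {
    net <- generateNetwork(6, 1, 0.5, seed = 32)
    sm <- simulateSamples(net, 20, seed = 32)
    x <- as.matrix(sm)
    set.seed(1)
    xp <- x[sample(nrow(x)), ]
    for (m in c("pearson", "spearman", "kendall", "bicor"))
        expect_equal(as.matrix(correlationAssociation(sampleMat(x), m)),
                     as.matrix(correlationAssociation(sampleMat(xp), m)),
                     tolerance = 1e-10)
    expect_equal(as.matrix(partialCorrelation(sampleMat(x))),
                 as.matrix(partialCorrelation(sampleMat(xp))),
                 tolerance = 1e-8)
})

test_that("the method registry gates sample-size preconditions", {
    expect_equal(methodMinSamples("mi"), 4L)
    expect_gte(methodMinSamples("pclrcmi"), 6L)
    expect_equal(methodMinSamples("pearson"), 3L)
    net <- generateNetwork(5, 0, 0.5, seed = 33)
    sm <- simulateSamples(net, 10, seed = 33)
    for (m in c("pearson", "clrp", "mrnet", "genie3"))
        expect_s4_class(inferAssociation(sm, m, seed = 1), "AssociationMatrix")
    expect_error(inferAssociation(sm, "nosuch"), "unknown")
})
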