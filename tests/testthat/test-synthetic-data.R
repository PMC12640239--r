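test_that("generated networks have the forced edge budget and structure", {
    # 3-node chain, no extras, pure mass action
    net <- generateNetwork(3, nExtraEdges = 0, mmFraction = 0, seed = 1)
    internal <- Filter(function(r) !r@sink, reactions(net))
    expect_length(internal, 2)
    expect_true(all(vapply(internal, function(r) r@law, character(1)) ==
                    "mass_action"))
    adj <- as.matrix(networkToAdjacency(net))
    deg <- colSums(adj)
    sinks <- Filter(function(r) r@sink, reactions(net))
    expect_setequal(unlist(lapply(sinks, function(r) r@substrates)),
                    nodeNames(net)[deg == 1])

    # n - 1 + extra internal edges, connected projection
    net10 <- generateNetwork(10, nExtraEdges = 2, seed = 7)
    a10 <- as.matrix(networkToAdjacency(net10))
    expect_equal(sum(a10[upper.tri(a10)]), 11)
    g <- igraph::graph_from_adjacency_matrix(a10, mode = "undirected")
    expect_true(igraph::is_connected(g))

    # determinism and the complete-graph budget guard
    expect_equal(generateNetwork(10, 2, 0.5, seed = 7),
                 generateNetwork(10, 2, 0.5, seed = 7))
    expect_error(generateNetwork(4, nExtraEdges = 10), "budget")
})

test_that("adjacency connects all participants of a reaction", {
    # A + B -> C: edges A-C, B-C and A-B (co-substrates share the reaction)
    net <- metabolicNetwork(c("A", "B", "C"), list(
        reaction("r1", c("A", "B"), "C", "mass_action", c(k = 1))))
    m <- as.matrix(networkToAdjacency(net))
    expect_equal(sum(m[upper.tri(m)]), 3)
    expect_equal(m, t(m))
    # sink reactions contribute no edges
    net2 <- metabolicNetwork(c("A", "B"), list(
        reaction("r1", "A", "B", "mass_action", c(k = 1)),
        reaction("out", "B", law = "mass_action", params = c(k = 0.1),
                 sink = TRUE)))
    expect_equal(sum(as.matrix(networkToAdjacency(net2))), 2)
})

test_that("zero perturbation gives identical nonnegative steady-state rows", {
    net <- generateNetwork(6, 1, 0.5, seed = 11)
    sm <- simulateSamples(net, 4, perturb = 0, seed = 5)
    v <- as.matrix(sm)
    expect_true(all(is.finite(v)) && all(v >= 0))
    for (i in 2:4) expect_equal(v[i, ], v[1, ], tolerance = 1e-8)
})

test_that("reversible isolated pair reaches the closed-form equilibrium", {
    k1 <- 2.3; k2 <- 0.7
    net <- metabolicNetwork(c("A", "B"), list(
        reaction("f", "A", "B", "mass_action", c(k = k1)),
        reaction("b", "B", "A", "mass_action", c(k = k2))))
    sm <- simulateSamples(net, 1, perturb = 0, seed = 1)
    v <- as.matrix(sm)[1, ]
    expect_equal(unname(v["B"] / v["A"]), k1 / k2, tolerance = 1e-4)
    # mass conservation on the closed system (initial total 10 + 1)
    expect_equal(unname(sum(v)), 11, tolerance = 1e-5)
    # state is a steady state of the rate equations
    expect_lt(steadyStateResidual(net, v), 1e-6)
})

test_that("perturbed parameters stay inside the stated band", {
    net <- generateNetwork(5, 0, 0.5, seed = 3)
    sm <- simulateSamples(net, 8, perturb = 0.1, seed = 9)
    f <- attr(sm, "paramFactors")
    expect_true(all(f >= 0.9 & f <= 1.1))
    # identical seeds reproduce samples exactly
    sm2 <- simulateSamples(net, 8, perturb = 0.1, seed = 9)
    expect_identical(as.matrix(sm), as.matrix(sm2))
})

test_that("condition shifts scale only the targeted reactions", {
    net <- generateNetwork(8, 0, 1, seed = 4)   # all Michaelis-Menten
    ids <- vapply(Filter(function(r) !r@sink, reactions(net)),
                  function(r) r@id, character(1))
    shift <- data.frame(reaction = ids[1], vmaxMult = 1000, kmMult = 2.5)
    aged <- applyCondition(net, shift)
    r0 <- reactions(net)[[1]]; r1 <- reactions(aged)[[1]]
    expect_equal(unname(r1@params["Vmax"] / r0@params["Vmax"]), 1000)
    expect_equal(unname(r1@params["Km"] / r0@params["Km"]), 2.5)
    for (i in seq_along(reactions(net))[-1])
        expect_identical(reactions(aged)[[i]], reactions(net)[[i]])
    # identity multipliers give back an equal network
    same <- applyCondition(net, data.frame(reaction = ids[1],
                                           vmaxMult = 1, kmMult = 1))
    expect_equal(same, net)
    # mass-action reactions cannot be targeted
    netMa <- generateNetwork(5, 0, 0, seed = 4)
    maId <- reactions(netMa)[[1]]@id
    expect_error(applyCondition(netMa, data.frame(
        reaction = maId, vmaxMult = 2, kmMult = 1)), "mass action")
})

test_that("CSV and JSON round-trips preserve objects and align names", {
    net <- generateNetwork(6, 1, 0.5, seed = 8)
    adj <- networkToAdjacency(net)
    sm <- simulateSamples(net, 5, seed = 8)

    td <- withr_like_tempdir <- tempfile(); dir.create(td)
    ap <- file.path(td, "adj.csv"); sp <- file.path(td, "samples.csv")
    writeAdjacency(adj, ap); writeSamples(sm, sp)
    back <- loadReference(ap, sp)
    expect_equal(as.matrix(back$adjacency), as.matrix(adj))
    expect_equal(as.matrix(back$samples), as.matrix(sm),
                 tolerance = 1e-12, ignore_attr = TRUE)

    # shuffled sample columns are reordered to adjacency order, with a note
    shuf <- as.matrix(sm)[, rev(nodeNames(sm))]
    writeSamples(new("SampleMatrix", values = shuf), sp)
    expect_message(back2 <- loadReference(ap, sp), "reordering")
    expect_identical(nodeNames(back2$samples), nodeNames(adj))

    # network JSON round trip
    np <- file.path(td, "net.json")
    writeNetworkJSON(net, np)
    expect_equal(readNetworkJSON(np), net)

    # malformed files are rejected with informative errors
    m <- as.matrix(adj); m[1, 2] <- 1; m[2, 1] <- 0
    utils::write.csv(as.data.frame(m), ap)
    expect_error(readAdjacency(ap), "symmetric")
    bad <- as.matrix(sm); bad[2, 3] <- NA
    utils::write.csv(data.frame(sample_id = 1:5, bad, check.names = FALSE),
                     sp, row.names = FALSE)
    expect_error(readSamples(sp), "row 2")
    unlink(td, recursive = TRUE)
})
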