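Package: MetNetBench
Title: Simulation-Based Benchmarking of Metabolomic Network Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates kinetically parameterized metabolic reaction networks,
    simulates steady-state metabolite concentration samples under parameter
    perturbation, infers association networks with correlation-,
    information-, regression- and resampling-based algorithms (Pearson,
    Spearman, Kendall, biweight midcorrelation, partial correlation,
    k-nearest-neighbour mutual information, CLR, MRNET, tree-ensemble
    importance, PCLRC), and scores inferred networks against the ground
    truth with pairwise metrics (F1, MCC, FDR, AUROC, AUPR at optimal
    thresholds) and centrality-based comparisons (degree, betweenness,
    harmonic closeness, PageRank). Includes an aspirational-network
    calibration sweep relating metric behavior to signal level, and a
    bootstrapped consensus procedure for differentiating metabolic
    conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    MASS,
    deSolve,
    igraph,
    ranger,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
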