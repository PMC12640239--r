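---
title: "MetNetBench: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MetNetBench: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

MetNetBench benchmarks network inference algorithms (NIAs) against a
simulated metabolic ground truth. This vignette is the package's account of
the science behind each component: the kinetic model the data generator
implements, the estimators in the inference panel, the evaluation
conventions, and the choices made where the design was genuinely open.

```{r setup}
library(MetNetBench)
```

# The synthetic ground truth

## Network model

`generateNetwork()` emulates the class of curated kinetic pathway models
used as inference references: sparse, largely tree-like networks with a few
cycles and mixed kinetics. It draws a random recursive spanning tree over
the metabolites, orients every reaction away from a designated core (root)
metabolite, and closes `nExtraEdges` cycles with additional reactions
oriented from shallower to deeper nodes. Each internal reaction is
Michaelis–Menten with probability `mmFraction` (rate
$v = V_{max}[S]/(K_m + [S])$, single substrate) and mass action otherwise
($v = k \prod_s [S_s]$). Michaelis–Menten reactions are restricted to a
single substrate by the class validity rule; multi-substrate chemistry is
expressed with mass action.

Two fluxes keep the system biologically sensible at steady state:

* a constant **influx** at the core metabolite. Without a source, a network
  with removal reactions relaxes to the all-zero state, which carries no
  correlation signal; real pathway models hold nonzero stationary
  concentrations precisely because mass flows through them. The influx rate
  is drawn log-uniformly from $[0.01, 0.05]$ h$^{-1}$, deliberately below
  every reaction's saturable capacity ($V_{max} \ge 0.1$) so that a
  positive steady state always exists even when all throughput is routed
  through one saturable reaction.
* first-order **efflux** at every terminal (degree-1) node *and* at every
  node with no onward reaction. The second clause matters for cyclic
  networks: an extra edge can give a node two incoming reactions and none
  outgoing; without removal such a node accumulates mass indefinitely and
  the system has no steady state.

Parameter ranges ($k, V_{max}$ log-uniform $[0.1, 10]$; $K_m$ log-uniform
$[0.5, 5]$; efflux $[0.05, 0.5]$) keep the stiff system integrable and
concentrations of order $10^{-3}$–$10$.

The reference adjacency (`networkToAdjacency()`) connects all metabolites
participating in the same non-efflux reaction, so a two-substrate reaction
$A + B \to C$ induces the edges A–C, B–C *and* A–B. This is the inclusive
reading of "reaction partners are connected"; it is pinned by a test so the
convention cannot drift.

## Steady-state simulation

`simulateSamples()` multiplies every kinetic parameter (including efflux
and influx rates) by an independent uniform draw from
$[1 - p,\, 1 + p]$ (default $p = 0.10$) and integrates the mass-balance
ODE system with `deSolve::lsodar` (adaptive, handles stiffness; absolute
tolerance $10^{-9}$, relative $10^{-6}$). Initial concentrations are 1.0
everywhere and 10.0 at the core metabolite; the simulation runs at most
`tEnd = 90` simulated hours.

Steady state is declared when the scaled derivative criterion

$$\max_i \frac{|dC_i/dt|}{\max(C_i, 10^{-12})} < 10^{-6}$$

holds; the integrator monitors it as a root function (after a 1 h burn-in)
and stops early when it fires. If the slowest relaxation mode of a sampled
network is too slow for 90 h — time constants up to $1/0.05 = 20$ h occur
at the bottom of the efflux range — the integrated state is refined by a
damped Newton iteration on the rate equations toward the same fixed point.
The criterion value actually achieved is re-evaluated from the rate
equations at the returned state and exposed as the `ssRatio` attribute, so
callers can verify rather than trust it. Negative transients smaller than
$10^{-9}$ in magnitude are clipped to zero; anything larger aborts with an
error naming the sample.

Closed systems (no influx/efflux), used for the mass-conservation and
closed-form equilibrium checks, converge through the root criterion during
integration; the Newton step only engages when the criterion is not yet
met, so conservation is not disturbed in those tests.

## Condition shifts

`applyCondition()` produces a modified copy of a network in which selected
Michaelis–Menten reactions have $V_{max}$ and $K_m$ multiplied — the aged
(sarcopenia-like) condition of the prostaglandin-degradation scenario uses
×1000 and ×2.5 respectively. Mass-action reactions cannot be targeted;
untouched reactions are bit-identical.

# The inference panel

All NIAs return a symmetric `AssociationMatrix` with zero diagonal, in one
of two families: `signed_correlation` (entries in $[-1, 1]$) or
`nonnegative`. Downstream consumers absolute-value signed matrices before
ranking or thresholding; the signed matrix is preserved for reporting.

* **Correlations** (`correlationAssociation()`): Pearson, Spearman and
  Kendall via `stats::cor`; biweight midcorrelation implemented with the
  standard median/MAD biweight and the usual 9-MAD tuning constant.
  Constant columns yield zero association with a message.
* **Partial correlation** (`partialCorrelation()`): $-P_{ij}/\sqrt{P_{ii}
  P_{jj}}$ from the Moore–Penrose pseudoinverse $P$ of the sample
  covariance. The pseudoinverse is the minimal-assumption route when
  $n \le p$; an optional shrinkage argument blends the covariance toward
  its diagonal first (off by default).
* **Mutual information** (`mutualInformation()`): the Kraskov
  k-nearest-neighbour estimator (variant 1), $k = 3$ by default, in nats.
  kNN estimators are undefined under exact ties, so a deterministic seeded
  jitter of magnitude $10^{-10}$ standard deviations is added first.
  Negative estimates are clipped to zero. The estimator is validated
  against the Gaussian closed form $-\tfrac{1}{2}\ln(1 - \rho^2)$ at
  $n = 2000$.
* **CLR** (`clrTransform()`): the symmetric z-score form of the original
  algorithm — row z-scores with the diagonal excluded, floored at zero,
  combined as $\sqrt{z_i^2 + z_j^2}$. Zero-variance rows get z-scores of
  zero. The z-score form is assumed since several variants circulate.
* **MRNET** (`mrnet()`): greedy MRMR per target with the *difference*
  criterion (relevance minus mean redundancy to the selected set), which is
  the common formulation and stays stable as redundancy approaches zero;
  each feature's score is its criterion value at selection time, floored at
  zero, and the matrix is symmetrized by the elementwise maximum.
* **Tree importance** (`treeImportance()`): per-target random-forest
  regressions (`ranger`), impurity importance normalized per target,
  symmetrized by the maximum. Defaults are 100 trees (a desk-scale default
  below the 1000-tree settings typical of GENIE3 runs; configurable) with
  square-root predictor subsampling and no depth cap.
* **PCLRC** (`pclrc()`): per iteration, draw 75% of the samples without
  replacement, compute the base association (Pearson by default; MI
  expressible), CLR-transform it, and mark the top 30% of off-diagonal
  pairs; the output is each pair's marking frequency over (by default)
  1000 iterations. Marking is global over pairs; a `perNode` flag switches
  to per-row marking since the original description is ambiguous on this
  point. Note the structural consequence: every iteration marks *exactly*
  the top fraction, so the mean output frequency equals that fraction
  regardless of the data — an algorithmic ceiling that the tests pin down
  explicitly.

Concentrations are used raw (no log transform) by default; all methods
accept any nonnegative sample matrix, so callers may transform beforehand.

# Evaluation conventions

All edge-level scoring operates on the $n(n-1)/2$ unordered off-diagonal
pairs — the evaluation is undirected.

* **Thresholding** is strict: edge iff $|A(x,y)| > \tau$.
* **Optimal threshold**: candidates are the midpoints between consecutive
  sorted unique $|A|$ values plus one candidate below the minimum and one
  above the maximum; ties resolve to the smallest $\tau$. This scan is
  exact — no grid resolution parameter.
* **Degenerate metrics** return defined values rather than NaN: F1 is 0
  when $2TP + FP + FN = 0$; MCC is 0 when any denominator factor is 0; FDR
  is 0 when nothing is predicted (no predictions, no false discoveries).
* **AUROC** is the Mann–Whitney rank statistic with averaged tie ranks;
  **AUPR** is the non-interpolated step-wise sum with tied scores grouped
  into blocks, avoiding the known optimistic bias of interpolated PR
  curves. With all scores equal, AUROC is 0.5 and AUPR equals the edge
  prevalence. The step-wise average-precision estimator carries a small
  *upward* bias under a random ranking when the positive count is low; it
  is negligible at realistic network sizes (below 0.01 at 40 nodes) and
  the null-behavior checks are run at that scale.

# Centrality comparison

`centrality()` computes four measures on binary networks:

* **degree**, normalized by $N - 1$ (the natural choice so a fully
  connected node scores 1; a switch to $N$ is provided since "total number
  of nodes" is ambiguous);
* **betweenness**, unnormalized, endpoints excluded, unordered pairs,
  unreachable pairs contributing zero (scale cancels in MAE comparisons
  between same-size graphs);
* **closeness** in the harmonic form $\frac{1}{N-1}\sum_j 1/d_{ij}$ with
  $1/\infty = 0$ — deliberately the mean-of-inverse-distances form, which
  is well defined on disconnected graphs without special-casing (it
  differs from classical closeness, the inverse of the mean distance);
* **PageRank** by power iteration on
  $R_i = \alpha \sum_j Adj_{ij} R_j / \deg(j) + (1-\alpha)/N$ with
  $\alpha = 0.85$, tolerance $10^{-10}$ on the L1 residual, and at most
  1000 iterations (non-convergence is an error carrying the last
  residual). Mass at isolated (dangling) nodes is redistributed uniformly,
  so the vector always sums to 1 exactly.

`centralityError()` reports per-node residuals (inferred − reference;
positive means overestimated) and their MAE, so systematic patterns — e.g.
central nodes underestimated, distal nodes overestimated — can be
inspected by joining residuals with the reference centralities.

# Aspirational calibration

`aspirationalMatrix()` constructs association matrices of controlled
quality: one $U[0,1]$ draw per unordered pair (mirrored, so the matrix is
exactly symmetric — one draw rather than two keeps symmetry without
averaging artifacts) plus $signal \times Adj(x,y)$. Entries lie in
$[0, 1 + signal]$; at signal 1 every true edge outranks every non-edge, so
every metric attains its optimum — a useful end-to-end sanity bound.
`signalSweep()` traces all metrics over fifty levels $0.02, 0.04, \ldots,
1.00$ (zero excluded by default, includable by passing it explicitly) with
100 matrices per level, and summarizes each level by the mean and the
2.5th–97.5th percentile interval. Centrality within the sweep is computed
after binarizing at the F1-optimal threshold against the true adjacency —
the best-case framing, so the sweep characterizes the metrics, not a
thresholding heuristic.

# Bootstrapped differentiation

`bootstrapConsensus()` draws `bootstrapSize` samples *with replacement*
(unlike PCLRC's without-replacement subsampling — the two are deliberately
distinct code paths), infers a network per draw (default Pearson + CLR),
binarizes it, and keeps edges present in strictly more than 50% of the
networks. Binarization inside bootstraps is the per-bootstrap F1-optimal
threshold when a reference adjacency is supplied; without one, a fixed
correlation threshold would be meaningless on CLR z-scores, so a rank-based
top-$k$ rule is used instead ($k$ = the reference edge count or
user-supplied). `differentialEdges()` splits the symmetric difference of
two conditions' reliable sets by side; `splitHalfAgreement()` re-uses the
already-generated networks (first half vs second half by index) as a quick
internal-reliability check; `edgePresenceTrace()` counts an edge's
occurrences so specific reactions can be interrogated directly.

# Seeds and reproducibility

Every stochastic operation takes an explicit seed and restores the
caller's RNG state. Grid and sweep cells derive per-cell seeds by hashing
(method, sample size, repetition) with the master seed, so results are
identical regardless of execution order and the grid is resumable from its
manifest without recomputation.

# What the generator does and does not emulate

The generator reproduces the *class* of the reference model — sparsity,
tree-plus-cycles topology, mixed kinetics, parameter perturbation at ±10%,
steady-state sampling, condition shifts — but not any particular curated
model: real kinetic parameterizations, metabolite aggregation (e.g. lipid
species pooled under one node), compartmentalization, measurement noise
and missingness are all absent. Passing tests therefore demonstrate
correctness of the algorithms and their contracts under clean, known
conditions; they do not certify performance on experimental data, where
the inference problem is strictly harder.

Problem sizes in the test suite and acceptance script (networks of 10–40
nodes, pools of 50–120 samples, 10–200 repetitions) are chosen to make the
checked properties sharp at interactive runtimes; all of them scale up by
argument.

# Known limitations

* Directed inference is out of scope: all evaluation relaxes edge
  direction, and GENIE3-style directed importances are symmetrized.
* No significance testing: thresholds are chosen by criterion
  maximization against a reference, not by p-values; differential edges
  carry no inferential guarantee.
* The ODE right-hand side is plain R; for networks beyond a few hundred
  nodes a compiled rate function would be the next step.
* Michaelis–Menten reactions are single-substrate; bi-substrate enzymatic
  kinetics (ternary-complex, ping-pong) are not modeled.
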