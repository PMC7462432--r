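---
title: "Predicting adherence from resting-state connectome topology: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting adherence from resting-state connectome topology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AdhereNet)
```

## The analysis in one paragraph

AdhereNet asks whether the organization of a person's resting-state
functional brain network, measured *before* a mental-training program,
predicts how well they will adhere to it (home-practice sessions completed
on a 0--20 scale, classes attended on 0--4). Each participant contributes a
parcellated BOLD time-series matrix (timepoints x ROIs). From it the
pipeline builds the weighted Pearson connectome, binarizes it over a grid
of correlation thresholds, computes binary graph metrics at each threshold,
tests every metric against the adherence scores with permutation
correlation tests under Benjamini--Hochberg FDR control, and finally trains
four classifiers to discriminate high from low adherence using nodal
metrics at robustly significant nodes.

## Connectome construction and binarization

The weighted connectome is the matrix of pairwise Pearson correlations
between ROI time series, diagonal fixed at zero. Binarization keeps an edge
where the correlation **strictly exceeds** the threshold T:

\[ a_{ij} = \begin{cases} 1 & r_{ij} > T \\ 0 & \text{otherwise} \end{cases} \]

Three deliberate readings of this rule:

* **Signed, not absolute.** Negative correlations never create edges at the
  default settings. The printed form of the rule compares the raw
  correlation with the threshold, so a strongly anti-correlated pair is
  "no connection". An absolute-value variant (`|r| > T`) is available via
  `runConfig(absoluteThreshold = TRUE)` and every result table records
  which mode was used, but it is off by default.
* **Strict inequality.** Ties at the threshold go to 0 ("otherwise"), so
  a matrix whose largest correlation is exactly 0.5 yields an empty graph
  at T = 0.5.
* **No Fisher transform, no global-signal regression.** The pipeline's
  entry point is the parcellated series; upstream preprocessing choices are
  out of its scope.

The default grid is T = 0.05 to 0.50 in steps of 0.05. There is no optimal
single threshold: lenient cuts admit noisy weak edges, stringent cuts
fragment the graph, so every statistic is carried across the full sweep and
conclusions rest on consistency. Thresholds above 0.5 are allowed but
trigger a warning (risk of retaining physiologically weak connections).
Because the rule is a strict cut on fixed weights, the ten graphs are
nested and edge counts are non-increasing in T -- a property the test suite
asserts on random connectomes.

## Graph metrics

All metrics operate on the undirected binary graph; `n` is the node count.

* **Degree centrality** `D_i`: row sums of the adjacency; the "hubness"
  measure.
* **Clustering coefficient** `C_i = 2 L_i / (K_i (K_i - 1))` with `L_i` the
  triangle count through node i, `K_i` its degree; the mean over all nodes
  is the global value. `C_i = 0` when `K_i < 2` -- the formula is 0/0 there
  and the zero convention keeps means defined on sparse graphs.
* **Global efficiency**: mean inverse geodesic (hop-count) distance over
  ordered node pairs; disconnected pairs contribute `1/Inf = 0`. This
  matters because stringent thresholds do fragment the networks, and the
  statistic must stay defined there.
* **Local efficiency** of node i: the global efficiency of the subgraph
  *induced by the neighbors of i* (i itself excluded), 0 for degree < 2.
  Paths are confined to the induced subgraph. This is implemented in
  compiled code (`src/metrics.cpp`) with a word-parallel breadth-first
  search; note that some graph libraries implement a different variant
  (paths in the full graph minus the vertex), which does **not** equal this
  definition -- the test suite pins the induced-subgraph reading against an
  independent Floyd--Warshall oracle.
* **Modularity (Q)**: Louvain community detection repeated `louvainReps`
  times (default 150) with seeds derived deterministically from the run
  seed; each partition is scored with the Newman--Girvan Q and the mean is
  reported. Partitions themselves are discarded -- only the quality
  statistic enters the analysis. The resolution parameter is fixed at 1.
  An edgeless graph gets Q = 0 with a warning rather than an error so
  sweeps never crash at extreme thresholds. Louvain is greedy: the tests
  assert that reported Q never exceeds the exhaustive-partition optimum
  (checked up to n = 8) and that it attains the optimum exactly on
  modular graphs, but exact optimality on arbitrary graphs is not a
  property a heuristic can promise.
* **Binarized system segregation**: with nodes partitioned into the five
  canonical resting-state networks (subcortical, sensory, default mode,
  attention/executive, language/memory),

  \[ S = \frac{\bar z_w - z_b}{\bar z_w} \]

  where `z_w` is the realized within-network edge count divided by the
  possible within count, averaged over the five networks, and `z_b` is the
  between-network edge count divided by the possible between count. `S` is
  undefined (a classed error; recorded as missing inside sweeps) when no
  within-network edge exists.

**Pooled versus pairwise between-density.** The between term can be read
two ways: all between-network pairs pooled into one class (one ratio), or
a density per network pair averaged over the ten pairs. The package
implements both (`runConfig(segregationBetween = ...)`); pooled is the
default because the defining sentence treats "between subnetworks" as a
single class. With equal network sizes the two coincide; with unequal
sizes they differ and the choice is recorded in the run log.

## Statistical inference

Every (metric, scope, threshold, group, outcome) cell is tested with a
two-sided permutation correlation test: the observed Pearson r against
`nPerm = 1000` random permutations of the adherence vector, with the
add-one estimator

\[ p = \frac{1 + \#\{|r_{perm}| \ge |r|\}}{nPerm + 1}. \]

Consequences worth stating explicitly:

* The attainable floor is `1/1001 = 9.99e-4`; p = 0 is never reported.
* The test is two-sided via `|r|` because both positive (clustering,
  segregation) and negative (global efficiency, some hubs) associations
  are scientifically expected.
* The identity permutation is not excluded; its probability is negligible
  and excluding it would bias the estimator.
* Permutations are drawn independently per test from a seed derived
  deterministically from the run seed (`deriveSeed`), so scans are exactly
  reproducible and no two tests share a permutation stream.

**FDR families.** BH correction is applied over (a) the 131 nodes within
one threshold for nodal scans and (b) all global metrics x thresholds
within one group/outcome for global scans. The family choice is a genuine
degree of freedom ("corrected for multiple comparisons" does not pin it
down); both choices are recorded in every results file. Cells whose metric
is constant across participants (e.g. clustering identically zero in a
fragmented graph) or missing (undefined segregation) are excluded from the
family rather than imputed.

**Robust nodes.** A node is robust when it stays FDR-significant at
`minSigThresholds` or more thresholds. The default is 3; the stricter
full-range rule (significant across the whole 0.05--0.5 sweep) is available
as `minSigThresholds = 10`. Asking for more thresholds than the grid has is
answered with a warning and a provably empty set. A note on discreteness:
with 1,000 permutations the smallest attainable p is 9.99e-4, while the
rank-1 BH cut at q = 0.05 over 131 nodes is 3.8e-4 -- a single node can
therefore never be significant alone; at least three nodes must sit at the
permutation floor together before BH can fire. This is an intrinsic
property of discrete permutation p-values combined with step-up FDR, not a
bug; it makes the nodal scan conservative on nearly-null data.

## Classification

Adherence is binarized at the homework cutoff: strictly more than 10
completed assignments is "high", everything else (including exactly 10) is
"low". Features are the nodal clustering and degree values of the robust
nodes, read at the reference threshold T = 0.35 (the threshold highlighted
for visualization; configurable). A quarter of participants is held out in
a stratified draw (largest-remainder apportionment per class, deterministic
given the seed). Backward elimination -- drop the feature whose removal
least harms the LOOCV accuracy of a 100-tree random forest, while accuracy
does not decrease, down to a configurable floor -- runs **on the training
partition only**; selecting features on data that includes the hold-out set
leaks information, and the test suite contains a deliberate leakage variant
demonstrating the inflation the guard prevents. Ties in the stop rule
continue elimination (prefer the simpler model), so redundant duplicated
features are pruned; on pure-noise tables the procedure usually, but not
always, runs down to the floor because LOOCV accuracy fluctuates.

Four classifiers are compared: random forest (100 trees), AdaBoost.M1 with
depth-1 decision stumps (50 rounds, implemented in the package), a single
decision tree, and Gaussian naive Bayes. LOOCV accuracy on the training set
is computed once per configured seed (default five); the fold layout is
deterministic and the seeds drive only classifier-internal randomness, so
the three deterministic classifiers repeat the same score with zero
confidence width -- visible in the report rather than hidden. The pooled
mean over all classifier x seed scores (4 x 5 = 20) is reported alongside
the per-classifier means with 95% normal-approximation half-widths. ROC
curves are built from the seed-averaged held-out scores by sweeping the
decision threshold; the trapezoidal AUC equals the Mann--Whitney
concordance probability (ties counting one half), which the tests assert to
1e-10. A single-class hold-out set yields a missing AUC with a warning, not
a crash. Hyperparameters not fixed by the protocol keep their ecosystem
defaults, pinned in code.

## The synthetic cohort generator

No neuroimaging data ships with the package; the generator plants the
statistical structure the analysis is supposed to detect, so every stage is
testable end to end with known ground truth.

Construction (per participant p): draw a coupling weight
`w_p ~ N(couplingMean, couplingSd^2)` truncated at zero; draw one latent
standard-Gaussian series per network plus one global series; ROI i in
network s follows

\[ x_i(t) = w_p \, \ell_s(t) + g \, \gamma(t) + \varepsilon_i(t), \qquad
   \varepsilon_i(t) \sim N(0, \sigma^2). \]

The latent-factor form guarantees a positive-semidefinite covariance and
gives one scalar knob per participant. Within-network correlation is
`(w_p^2 + g^2) / (w_p^2 + g^2 + sigma^2)` and between-network correlation
`g^2 / (w_p^2 + g^2 + sigma^2)`: as `w_p` grows, within-network coupling
rises *and* between-network coupling falls, which is exactly the
"more segregated network" phenotype. Homework is
`round(clip(a + b w_p + e, 0, 20))` with the intercept `a` chosen so the
expected mean sits near 10; attendance is generated analogously on 0--4.
Rounding and clipping are intentional: they produce the ties and ceiling
effects real questionnaire scores have. Group labels (meditation 29,
writing 22) share one set of generative parameters by default; a per-group
slope override exists for emulating group-specific effects.

**Calibration (fixed once).** The defaults are `couplingMean = 1`,
`couplingSd = 0.3`, `globalWeight = 0.3`, `noiseSd = 1`,
`effectSlope = 10`, `effectNoiseSd = 3`. They were chosen once from a
calibration sweep with two aims: the pooled correlation between mean
clustering and homework lands in the 0.3--0.5 band typical of reported
global-metric effects at n = 51, and the nodal robust set is recovered
reliably run after run. Those two aims trade off against each other -- both
scale with `b * sd(w) / sigma_e` -- and the defaults sit at the point where
recovery is dependable; the pooled correlation then averages ~0.45--0.5
rather than ~0.3. At these settings the sign structure of the global scan
is a structural property, not a coincidence: clustering, local efficiency
and segregation correlate positively with homework at essentially every
threshold, while global efficiency correlates negatively at lenient
thresholds (where the loss of between-module shortcuts dominates) and
positively at stringent ones (where surviving within-module density
dominates, all between-module edges being gone for everyone). The sign
crossover sits near the middle of the default grid -- the negative band
typically covers T = 0.05--0.30, six of ten thresholds, occasionally five
when the cell nearest the crossover flips -- so "global efficiency
negative at a majority of thresholds" holds in most but not every run.
This is a known divergence from real-data behavior, where between-network
correlations are strong enough to keep graphs globally connected across
the whole sweep and the negative association persists at stringent
thresholds; the generator's weak global signal (between-network r around
0.04--0.1) kills between-module edges by T = 0.2. The constants were fixed
before the acceptance checks were run and are deliberately not revisited.

**What the generator does not emulate.** Hemodynamics, temporal
autocorrelation, scanner drift, motion artifacts, spatially heterogeneous
network sizes, negative functional coupling, and individual differences in
parcellation quality. Passing tests therefore demonstrate that the
*pipeline* recovers planted covariance-adherence structure at realistic
sample sizes; they say nothing about whether real cohorts carry such
structure, and effect sizes on real data may be far smaller than the
calibrated defaults.

## Numerical and reproducibility choices

* All randomness flows from explicit seeds through `deriveSeed`, a
  Lehmer-style map onto `[1, 2^31)`; no hidden global RNG state survives a
  call, and identical seeds give byte-identical cohorts and scans.
* Written time series use `%.17g` so the text round trip is bit-exact.
* File dialects (comma/tab) are sniffed from the first line; decimal
  points only.
* ROI order is fixed by the first file in the manifest; all others must
  match labels exactly, with no silent reordering (positional metrics make
  reordering a silent corruption).
* `runPipeline` writes `run.json` with the package version, configuration,
  seed, and md5 digests of the inputs, sufficient to re-execute a run.
* Problem sizes in the test suite: module tests run mostly on 10--30
  participants with 15 ROIs; the statistical acceptance checks simulate 20
  study-scale cohorts (51 participants, 131 ROIs, 145 timepoints) per
  condition, 500 replicate datasets for the type-I check, and 200 random
  graphs for the metric-oracle suite -- sizes chosen so the full suite
  completes on a single CPU in well under half an hour while keeping the
  Monte-Carlo error of every asserted fraction far below its margin.

## Known limitations

* The Louvain mean Q is a heuristic lower bound on the true optimum.
* Permutation p-values are discrete; combined with BH this makes nodal
  scans conservative (see above), and exact FDR calibration arguments
  apply only marginally per test.
* The classifier stage at n = 51 (38 train / 13 held out) has wide
  sampling variability in held-out AUC; single-run AUCs should be read as
  descriptive, which is why the report carries cross-validation means with
  confidence half-widths alongside.
* The five-network affiliation is an input; deriving affiliations from
  data is out of scope.
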