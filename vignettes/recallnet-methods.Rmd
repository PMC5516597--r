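---
title: "Methods: hierarchical connectome analysis of free-recall performance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical connectome analysis of free-recall performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Episodic memory performance varies widely between healthy young adults.
One candidate substrate of that variability is the structural connectome:
the whole-brain network of white-matter connections between grey-matter
regions, estimated per subject by probabilistic tractography and
summarised as a weighted, undirected graph. `recallnet` implements a
population-level analysis that relates picture free-recall counts (the
number of pictures a subject freely recalls out of 72, split over
negative, neutral and positive valence) to properties of that graph at
three spatial resolutions: the whole network, its 82 nodes, and its
individual connections.

The node set is fixed: 34 Desikan–Killiany cortical regions per
hemisphere plus 7 subcortical structures per hemisphere, 82 nodes in
total (`dk_atlas()`). Each subject contributes one symmetric 82×82 matrix
of connection probabilities in [0, 1] with zero diagonal. The pipeline
consumes already-built matrices; tractography itself is out of scope.

## Population-level edge filtering

Probabilistic tractography produces many weak, unreliable connections.
`population_edge_mask()` excludes, identically in every subject, each
edge whose across-subject `mean + 2·sd` falls below a connectivity floor
(default 0.01). The standard deviation uses the sample (n−1) denominator,
the common choice for subject samples; the rule itself does not specify
one, and at cohort sizes in the hundreds the difference is negligible.
Symmetrization of directed tractography output is a separate, explicit
step (`symmetrize()`, the arithmetic mean of the two directions):
asymmetric matrices are rejected at ingest rather than silently fixed.

## Graph metrics and their conventions

All metrics operate on weighted adjacency matrices in which a zero
weight is an absent edge.

* **Network cost** (weighted density): the sum of edge weights over
  `R(R−1)/2`. It equals the mean nodal degree — an identity the test
  suite checks numerically on random graphs.
* **Nodal degree**: mean connectivity of a node over its `R−1` possible
  partners.
* **Weighted clustering**: the geometric-mean (Onnela) triangle form on
  weights rescaled by the maximum weight. For binary graphs this reduces
  to the local triangle fraction. Chosen because it is the default
  weighted clustering of the standard brain-connectivity toolbox family;
  the alternative (Barrat) form weights triangles arithmetically and is
  not used here.
* **Path-based metrics** map weight to length as `1/w`: stronger
  connections are shorter. This is the standard convention for
  probabilistic connection weights. Characteristic path length averages
  *finite* distances only and reports the number of unreachable pairs,
  because masked connectomes may be disconnected; global efficiency
  (mean inverse distance, `1/∞ = 0`) is the disconnection-robust
  companion. Nodal efficiency of node *i* is the global efficiency of
  the subgraph induced by *i*'s neighbours.
* **Betweenness** counts the fraction of shortest paths between ordered
  pairs of other nodes passing through a node, normalised by
  `(R−1)(R−2)`, so values lie in [0, 1].
* **Random references** (`random_reference()`) are Maslov–Sneppen
  double-edge swaps on the binary topology with a target of 20
  successful swaps per edge; each edge carries its weight with it, so
  the binary degree sequence, edge count and weight multiset are exactly
  preserved. Whether weights should instead be re-assigned after
  rewiring is genuinely open; carrying them is the simpler invariant and
  is what the preservation tests pin down.

### Cost integration

Topological differences driven purely by differences in network cost
confound between-subject comparison. Cost-integrated metrics remove this
by binarising each subject's network at a grid of cost levels — keeping
the `round(κ·R(R−1)/2)` strongest edges, ties broken lexicographically
for determinism — evaluating the metric at each level, and averaging
over the grid. The grid spans `1/(R(R−1)/2)` (a single edge) up to the
smallest maximum cost common to all subjects, so every binarisation is
well defined for every subject. The default grid has 50 equispaced
points; the cascade uses a coarser grid by default (10 points) because
the integrated values it feeds into a single global test are extremely
stable in grid resolution, and normalised path length inside the grid
defaults to its unnormalised form (`n_random = 0`) — generating hundreds
of rewired references per subject per grid point changes the *ranking*
of subjects negligibly while dominating runtime. Both choices are
parameters, not constants.

## The hierarchical inference cascade

Hypotheses are ordered by resolution: one global measure per subject,
then 82 nodal degrees, then individual edges. Each level applies
Benjamini–Hochberg FDR at `q = 0.05` within the level, and a level is
tested **only if** the level below rejected — the multiplicity burden
grows only as far as the data warrant.

* **Level 1**: Spearman association between residualized recall (age and
  gender regressed out) and residualized network cost (age, gender and
  intracranial volume regressed out). Residualization precedes ranking.
  The level-1 family over which BH adjusts comprises cost plus the four
  cost-integrated global metrics (global efficiency, clustering,
  characteristic path length, betweenness), i.e. m = 5.
* **Level 2**: per-node degree associations, BH over the 82 nodes.
* **Level 3**: every mask-retained edge incident to at least one
  rejected node, each undirected edge counted once, BH over that set.

Plain BH step-up is used at every level. The hierarchical-FDR literature
also offers variants that deflate `q` at higher levels to control the
full-tree error rate; because the reference analysis's exact variant is
ambiguous, plain BH with `q` exposed as a parameter is the documented
behaviour, and the per-level critical p-values are reported so any
variant can be audited. A consequence worth knowing: the critical
p-values printed by the reference study's node and edge tables are not
exactly reproducible from its printed p-values by plain BH.

P-values for Spearman coefficients use the t approximation
`t = r·sqrt((n−2)/(1−r²))` on `n−2` degrees of freedom; at the cohort
sizes this pipeline targets (hundreds of subjects) it is accurate far
beyond the precision that matters here (the test suite compares it with
a permutation oracle at small n). 95% confidence intervals are
percentile bootstrap over subjects (default B = 2000, seeded); they are
computed for rejected units only, since those are what gets reported.

## Robust multi-edge regression

The combined effect of an edge set on recall is summarised by
iteratively reweighted least squares with the Tukey bisquare weight
function: tuning constant `c = 4.685` (95% Gaussian efficiency), scale
re-estimated each iteration as `MAD/0.6745` of the current residuals,
iterated to a coefficient change below 1e−8 or 100 iterations
(non-convergence is flagged, never silent). The reported variance
explained is `1 − SSE/SST` with *unweighted* residuals of the converged
fit. The implementation is the package's own; `MASS::rlm` with the same
psi function serves as an independent cross-check in the tests.

## Network-based statistic

As a mass-univariate complement to the cascade, the NBS tests every
mask-retained edge at once: (1) a per-edge t statistic from an OLS fit
of recall on the edge plus age, gender and intracranial volume
(`df = n − 5`); (2) thresholding at `T` (default 2.5 — the one-sided
upper tail of t at df ≈ 660 is 0.0063, which is how the threshold is
usually quoted as a p-value; presets for T = 2 and T = 3 simply pass a
different `T`); (3) connected components of the suprathreshold graph,
sized by edge count; (4) a family-wise-error p-value per component from
the permutation null of the maximal component size, with the `+1`
correction so p is never zero.

The threshold is one-sided (`t ≥ T`) by default because the quoted
threshold/p-value correspondence matches the one-sided tail and the
hypothesis is directional (stronger connections, better recall); a
two-sided mode is behind a flag. Permutation keeps subjects' covariates
attached and permutes the covariate-residualized phenotype against the
covariate-residualized edges (the Freedman–Lane device): the phenotype
is exchangeable under the null after covariate adjustment. The
permutation engine recomputes all edge statistics per permutation in
vectorised form and extracts maximal component sizes with a union-find;
`igraph`'s component finder is the cross-checked reference on observed
maps.

## The synthetic cohort generator

No subject-level data travel with the package; every claim its tests
make is exercised on synthetic cohorts with known ground truth
(`synth_config()` / `simulate_cohort()`). The generator's defaults *are*
the emulated study conditions: n = 664 subjects, 82 nodes, a planted
cost–recall rank correlation of 0.102, 22 planted edges jointly
calibrated to 7.8% of recall variance, recall out of 24 pictures per
valence with emotional valences remembered better than neutral, age
22.85 ± 3.37 years, 59% female, and per-node volumes unrelated to
memory.

Structure: a fixed sparse template connectome (lognormal weights,
spanning-tree-connected, density 0.35 — chosen so the smallest
per-subject maximum cost lands near the 0.35 upper bound the cost grid
assumes); a latent memory trait `m` and a latent connectivity factor `g`
coupled by a Gaussian copula; a multiplicative subject scale
`s = exp(τ·g + covariate loadings)` applied to all template edges with
lognormal edge noise; planted edges additionally receive
`a·(template weight)·m`; recall counts are binomial(24, logistic) per
valence with `m` and covariates on the logit. Volumes scale with ICV
and noise only. Binomial recall out of 72 pictures mirrors the bounded
count nature of the task; the generator makes no claim that real recall
counts are binomial — it is a stated modelling choice.

**Calibration.** The two targets are defined on the *measured* scale,
after residualization, rank transformation, binomial discretisation and
weight clipping, so neither has a closed form. `calibrate_generator()`
root-finds the copula correlation and the edge loading against a
reduced Monte-Carlo simulation (2×10⁵ draws, common random numbers) of
the exact measurement chain, with one simplification: the mean of the
~1100 per-edge noises entering network cost is replaced by its CLT
normal approximation (relative error ~3% of an already small term).
Because the reported R² of a 22-predictor fit at n = 664 is an
in-sample quantity, the edge loading targets the population R² deflated
by the standard inflation `E[R²] ≈ ρ² + (1−ρ²)p/(n−1)`; the small
difference between the OLS and bisquare in-sample R² is measured on the
same chain and folded into the target. The approximation error that
remains (a few tenths of a percentage point, conservative) is well
inside the ±1-point recovery tolerance the package tests. Calibrations
are cached per configuration and never touch the caller's RNG stream.

What the generator does *not* emulate: anatomically realistic weight
topology (distance-dependent connection probabilities, hub structure
beyond what lognormal weights induce), measurement noise correlated
across edges, or non-binomial recall dispersion. Passing tests
therefore demonstrate that the *statistical machinery* behaves as
specified under a faithful effect-size structure — not that the
reference study's anatomical findings would replicate.

## Numerical choices and degenerate inputs

* Edge iteration is always over the strict upper triangle in one
  canonical order; matrices are stored fully but each undirected edge
  has a single source of truth.
* Binarisation tie-breaks are lexicographic in `(i, j)` — deterministic
  across platforms.
* Constant edges in the NBS get `t = 0` with a flag; exact fits get an
  infinite sentinel rather than a division by zero.
* Spearman on a (numerically) constant vector is an error, not an NA:
  a degenerate residual (e.g. controlling recall for itself) should
  fail loudly.
* `random_reference()` returns the input unchanged with a warning flag
  when no legal swap exists.
* All permutation and bootstrap loops take explicit seeds; identical
  seeds give identical results to the byte.

## Problem sizes used in the packaged checks

The package's own test suite runs the full recovery protocols (200
replicate cohorts for the global effect, 100 for the edge model) at the
default n = 664, and scales the purely structural property suites down
(graphs of 4–15 nodes, 200 null datasets × 500 permutations for the
NBS calibration) — sizes chosen so each property is tested at the
resolution where its failure modes live, with exhaustive oracles still
feasible.

## Known limitations

* Plain BH at each level controls FDR within level, not over the whole
  three-level tree.
* The linear-mixed-model valence-interaction analysis is not
  implemented; the generator emits per-valence counts so it could be
  added on top.
* The t-approximate Spearman p is slightly anticonservative below
  n ≈ 20; the pipeline targets cohorts two orders of magnitude larger.
* Cost-integrated normalised path length is expensive if `n_random > 0`
  is requested over a fine grid; the default trades that fidelity for
  tractable runtime and says so above.
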