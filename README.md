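# recallnet

Structural-connectome correlates of episodic memory performance.

`recallnet` is an R package for relating picture free-recall counts to
weighted structural brain networks in large cohorts. It implements the
full population-level analysis chain for subjects × (82 × 82)
connectivity matrices built on the Desikan–Killiany + subcortical
parcellation:

* **Edge filtering** — exclude spurious connections at the population
  level: edge kept iff `mean(w_ij) + 2·sd(w_ij) ≥ 0.01` across subjects.
* **Weighted graph metrics** — network cost
  `κ = Σ_{i<j} w_ij / (R(R−1)/2)`, nodal degree
  `k_i = Σ_j w_ij/(R−1)` (mean degree ≡ cost), Onnela weighted
  clustering, characteristic path length and efficiency on `1/w` edge
  lengths, betweenness, degree-preserving random references, and
  cost-integrated variants over a density grid.
* **Hierarchical FDR cascade** — Spearman association of residualized
  recall with network cost (BH-adjusted within the 5-metric global
  family), then per-node degree (BH over 82 nodes), then per-edge tests
  on the connectivity profile of rejected nodes — each level gated on
  rejection at the level below.
* **Network-based statistic (NBS)** — per-edge OLS t statistics with
  age/gender/ICV covariates, suprathreshold components at `T = 2.5`
  (one-sided tail p = .0063 at df = 660), and FWE-corrected component
  p-values from a permutation null of maximal component size.
* **Robust multi-edge regression** — Tukey bisquare IRLS (`c = 4.685`,
  scale `MAD/0.6745`) summarising the variance in recall explained by
  an edge set.
* **Volumetry control** — per-node grey-matter volume associations
  (expected null).
* **Synthetic cohort generator** — cohorts with planted, calibrated
  effect sizes (global rank correlation, joint edge R², valence-graded
  binomial recall, covariate confounding, null volumes) so the whole
  pipeline is testable without subject-level imaging data.

Statistical results come back as tibbles; fitted objects have
`tidy()`, `glance()` and `autoplot()` methods.

## Worked example

Simulate a cohort with a strong planted effect and run the full
pipeline:

```r
library(recallnet)

cfg  <- synth_config(n = 300, rho_global = 0.2, edge_r2_target = 0.15)
co   <- simulate_cohort(cfg, seed = 11)

mask <- population_edge_mask(co$stack, floor = 0.01)
res  <- hierarchical_cascade(co$stack, mask, co$cohort,
                             global_family = FALSE, B = 200, seed = 1)
res
#> <recall_cascade> n = 300, q = 0.05
#>   level 1 (cost): r = 0.217, p = 0.00015, p_adj = 0.00015 (rejected)
#>   level 2: 76 of 82 nodes rejected
#>   level 3: 29 of 1130 edges rejected
```

The global cost–recall association (level 1) is rejected, so the
cascade descends: level 2 reports which of the 82 nodes' degrees track
recall after BH correction (the planted effect is a global
connectivity factor, so most nodes carry it), and level 3 tests the
mask-retained edges incident to those nodes, flagging 29 of 1130. At
realistic effect sizes (`rho_global = 0.102`) a typical single cohort
rejects only a handful of nodes or stops at level 1 — which is exactly
why the package's recovery checks average hundreds of replicate
cohorts.

The robust summary of the detected edge set:

```r
EV <- edge_values(co$stack, res$rejected_edges[, c("i", "j")])
ry <- residualize(co$cohort$recall_total,
                  co$cohort[, c("age", "gender")])
glance(robust_r2(ry, EV))
#> # A tibble: 1 × 6
#>   r_squared     n     p iterations converged     c
#>       <dbl> <int> <int>      <int> <lgl>     <dbl>
#> 1     0.203   300    29         44 TRUE       4.68
```

An in-sample R² over 29 *post-selection* predictors is optimistic; the
unbiased recovery number the package reports comes from fitting the
known planted edges (see below).

`run_pipeline()` wires all stages together and writes TSV reports plus
a JSON manifest; `inst/cli/recallnet.R` is a thin command-line front
end with `simulate` and `run` subcommands.

## Reference tables

`reference_associations()` loads the published per-node, per-edge and
global association tables of the reference study this package models
(under `inst/extdata/`); they feed the worked examples and the
consistency checks in `tests/testthat/test-acceptance.R`.
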