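---
title: "Structural covariance network analysis with covnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural covariance network analysis with covnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covnet)
```

## The model

A structural covariance network is a group-level graph over cortical
regions: across the subjects of a group, a morphometric measure (here,
cortical thickness over a parcellation such as the 68-region
Desikan–Killiany atlas) covaries between regions, and strong positive
covariance is read as a connection. covnet implements this construction
and the graph-theoretic analysis that conventionally follows it:

1. **Correlation.** For one group, the Pearson correlation `r_ij` between
   every pair of region columns gives a symmetric matrix `R`
   (`correlation_matrix()`). The diagonal is ignored throughout.
2. **Thresholding.** `R` is binarised at a target *density* (wiring cost)
   `d`: the `E = round(d N(N-1)/2)` strongest strictly positive
   correlations become undirected, unweighted edges
   (`threshold_at_density()`). Density follows the convention
   `K / (N(N-1))` with `K` counting both symmetric adjacency entries, so
   for 68 regions `d = 0.19` gives 433 edges. Negative and zero
   correlations are never admitted, because only positive morphometric
   correlations are plausibly mediated by direct connections. Because no
   single threshold is privileged, networks are built across a grid of
   densities (default 5–40% in 1% steps, `density_grid()`), and every
   metric becomes a curve over that grid summarised by its trapezoidal
   area under the curve (AUC).
3. **Graph metrics.** On each binary network: mean clustering coefficient
   `Cp`, characteristic path length `Lp`, global and local efficiency,
   Newman–Girvan modularity `Q` with a Louvain partition, betweenness
   centrality, and hub status (betweenness more than twice the network
   mean). Small-world coefficients normalise `Cp` and `Lp` by their means
   over an ensemble of degree-preserving rewired null networks:
   `gamma = Cp/Cp_rand`, `lambda = Lp/Lp_rand`, `sigma = gamma/lambda`;
   `sigma > 1` indicates small-world organisation.
4. **Robustness.** At a fixed comparison density (default 19%), resilience
   is summarised by the relative size of the largest connected component
   as nodes or edges are removed, either uniformly at random (mean over
   repetitions) or in decreasing order of betweenness (targeted attack).
5. **Inference.** Because each group yields one network per density, group
   differences cannot be tested subject-wise. Instead, subject-relabelling
   permutation tests rebuild the entire pipeline under `n_perm` random
   reassignments of subjects to groups (preserving group sizes) and refer
   the observed AUC difference to that null distribution, two-tailed.
   Scalar statistics at the fixed density (per-hub normalised betweenness,
   robustness values) use the same scheme via
   `permutation_test_scalar()`.

## Conventions and numerical choices

These cases are not fixed by the standard definitions, so the package
adopts explicit conventions:

- **Disconnected networks.** `Lp` averages over mutually reachable pairs
  only; this keeps it finite at the sparse end of the grid, where
  covariance networks routinely fragment. Efficiency handles
  disconnection natively (`1/Inf = 0`). Nodes of degree < 2 contribute 0
  (not `NA`) to the `Cp` and local-efficiency means, keeping denominators
  identical across groups.
- **Ties at the threshold** are broken by (smaller row index, smaller
  column index), so runs are reproducible and edge sets are nested across
  densities.
- **Exhausted positive correlations.** If fewer positive correlations
  exist than the density demands, the network is returned at the
  achievable density with a warning and a `truncated` flag, rather than
  padded with non-positive edges.
- **Null model.** Maslov–Sneppen double-edge swaps (10 attempted swaps per
  edge, 100 nulls by default) preserve each node's exact degree. The
  ensemble size and swap intensity are configuration knobs, since
  different null recipes can shift `gamma` and `lambda` slightly. With an
  identity ensemble (0 swaps) the coefficients are exactly 1, which the
  tests exploit as a limit case. If every null in an ensemble has zero
  clustering (possible for very sparse graphs), the coefficients are
  undefined at that density; profile code records `NA` and drops that
  density from AUCs — pairwise across the two groups being compared, so
  both integrals cover the same interval.
- **Modularity** is maximised by seeded Louvain with 20 restarts (best Q
  kept). The partition itself is reported, but no constraint is placed on
  the number of modules.
- **Targeted attacks** use the betweenness ranking of the *intact*
  network (static ordering); adaptive re-ranking after each removal is
  available via `recompute = TRUE`. Removal-order ties break by region
  index (nodes) or lexicographic endpoint pair (edges).
- **Random-failure curves** draw one removal permutation per repetition
  and evaluate its prefixes along the fraction grid. The removed set at
  each fraction is still uniform of the stated size, but each
  repetition's curve is monotone by construction, so the reported mean
  curve inherits the theoretical monotonicity exactly instead of only in
  expectation.
- **Permutation p-values** use the add-one rule
  `(1 + #{|null| >= |obs|}) / (n_perm + 1)`, which cannot return 0 and is
  valid at any `n_perm`. Relabellings preserve the observed group sizes.
  Bonferroni adjustment across the 8 network metrics is reported
  alongside raw p-values; both are emitted because no single correction
  family is canonical for this battery.
- **AUC** uses the trapezoidal rule on the density grid; a grid with
  fewer than two defined points yields AUC 0 with a warning.

## The synthetic cohort generator

Real cortical-thickness cohorts are rarely shareable, so the package
ships a generator that serves as ground truth for validation and as the
bundled demo study. A `covariance_spec()` describes one group: regions
are partitioned into modules with target correlation `r_within` inside a
module and `r_between` across modules, and optional *connector hub*
regions whose cross-module correlation is raised to `r_hub`. The implied
correlation matrix is repaired to positive semi-definiteness by
eigenvalue clipping when needed; the repair must move no entry by more
than 0.05, otherwise construction fails loudly. Subjects are then drawn
from a multivariate normal with per-region means (default 2.5 mm) and
standard deviations (default 0.25 mm), values typical of adolescent
cortical thickness.

The reference study conditions (`default_cohort_specs()`) mirror the
two-group design the pipeline targets: 68 regions in 4 modules, 43
"patient-spec" versus 73 "control-spec" subjects, a control group with
`r_within = 0.5` and two planted connectors at `r_hub = 0.35`, and a
patient group with `r_within` lowered to 0.35 and a partly relocated hub
set. Group effects are deliberately expressed through covariance
structure rather than mean shifts: every downstream statistic is
correlation-based, so mean shifts would be invisible to the pipeline.
In the validation suite, the planted-connector scenario uses a single
connector at `r_hub = 0.45` — a strongly covarying way-station whose
elevated cross-module correlation survives sampling noise at `n = 43` —
and the effect-recovery scenario halves `r_within` (0.5 to 0.25), a
covariance de-segregation large enough that a well-powered test should
detect it at these sample sizes.

What the generator does *not* emulate matters for interpretation: it
draws i.i.d. multivariate-normal subjects (no site, age or sex structure,
no measurement artefacts, no spatial autocorrelation along the cortical
sheet), and its planted topology is block-structured rather than
distance-dependent. Passing tests therefore demonstrate that the
pipeline recovers known covariance topology under clean sampling — not
that any particular clinical contrast will replicate.

## Validation design

The test suite validates each stage against an independent route:
metrics against brute-force oracles (exhaustive BFS, triangle counts and
shortest-path enumeration on graphs of up to 7 nodes), thresholding
against the closed-form edge-count contract, small-world coefficients
against analytic limit cases (identity ensemble, ring lattice, dense
random graphs), the permutation test against its type-I-error
calibration under a shared generating spec, and power against planted
effects. Simulation sizes are chosen to keep the default suite at
desk scale: type-I calibration uses 200 simulated studies of 20 regions
with 200 permutations each; power uses 25 studies, with the weakened
covariance planted in the smaller (n = 43) group as in a 43-vs-73
clinical design; the end-to-end demo uses the full 116-subject,
68-region cohort with a 5%-step grid, 100 permutations, 10 nulls and 50
robustness repetitions.

## Worked example

```{r example, eval = FALSE}
specs <- default_cohort_specs()
cohort <- generate_cohort(specs$control, specs$patient, 73, 43,
                          seed = 7, group_names = c("HC", "CD"))

# fixed-density network, hubs, small-world coefficients
net_hc <- cohort |> correlation_matrix("HC") |> threshold_at_density(0.19)
identify_hubs(net_hc)
small_world_params(net_hc, n_nulls = 100, seed = 1)

# density profiles and a permutation test on their AUCs
perm <- permutation_test_auc(cohort, c("e_glob", "e_loc", "q"),
                             grid = density_grid(0.05, 0.40, 0.05),
                             n_perm = 200, seed = 2)
tidy(perm)

# or everything at once, written to a run directory
cfg <- run_config(cohort, density_step = 0.05, n_perm = 200,
                  n_nulls = 20, n_reps = 200, seed = 3,
                  out_dir = "covnet_demo_run")
run_pipeline(cfg)
```

## Limitations

- The pipeline is binary and undirected by design; weighted or partial
  correlation variants are out of scope.
- Group-level construction means no subject-level network exists, so
  covariate adjustment and brain–behaviour correlations are not
  supported.
- Louvain is a heuristic; with few restarts on near-degenerate modular
  structure, `Q` can vary slightly between seeds. The seeded restart
  scheme makes any given run reproducible.
- Small-world coefficients depend on the null recipe; the
  degree-preserving swap ensemble is the field standard but not unique.
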