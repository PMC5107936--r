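# covnet

Group-level **structural covariance network** analysis of cortical
morphometry in R. Given a subject × region table of cortical thickness
(e.g. the 68 Desikan–Killiany gyral regions), covnet builds each group's
inter-regional Pearson correlation matrix, thresholds it into binary
networks across a density grid, and analyses their topology: small-world
coefficients against degree-preserving rewired null ensembles, global and
local efficiency, Newman–Girvan modularity, betweenness-based hub
detection, and robustness to random failures and targeted attacks. Group
differences are tested with subject-relabelling permutation tests on
area-under-curve (AUC) summaries across densities.

It is aimed at neuroimaging groups comparing two cohorts (patients vs
controls) whose networks exist only at the group level, so that standard
subject-wise statistics do not apply.

## The method in brief

For a group with subject × region values, the pipeline computes

- `R = (r_ij)`, the Pearson correlation between every pair of regions;
- `A(d)`, the binary network keeping the `E = round(d·N(N−1)/2)` strongest
  strictly positive correlations at density `d` (for `N = 68`, `d = 0.19`
  gives 433 edges; density is `K/(N(N−1))` with `K` counting both
  symmetric entries);
- on each `A(d)`: clustering coefficient `Cp`, characteristic path length
  `Lp`, global/local efficiency, modularity `Q`, betweenness, and the
  small-world coefficients `γ = Cp/Cp_rand`, `λ = Lp/Lp_rand`,
  `σ = γ/λ` against rewired null networks;
- each metric's AUC over the density grid (default 5–40%), compared
  between groups by permuting subject labels and recomputing the whole
  pipeline per permutation: `p = (1 + #{|null| ≥ |obs|})/(n_perm + 1)`,
  two-tailed;
- hubs (betweenness > 2× network mean) and attack/failure robustness
  curves at a fixed density (default 19%).

A synthetic cohort generator with planted covariance modules, connector
hubs and group effects provides ground truth for every stage.

## Worked example

```r
library(covnet)

specs <- default_cohort_specs()   # 68 regions, 4 modules, planted hubs
cohort <- generate_cohort(specs$control, specs$patient, 73, 43,
                          seed = 7, group_names = c("HC", "CD"))

net_hc <- cohort |> correlation_matrix("HC") |> threshold_at_density(0.19)
net_hc
#> <covnet_network> 68 regions, 433 edges (density 0.190)

small_world_params(net_hc, n_nulls = 50, seed = 1)
#> <covnet_smallworld> gamma = 4.333, lambda = 1.677, sigma = 2.583 (50 nulls)

head(identify_hubs(net_hc), 3)
#> # A tibble: 3 x 4
#>   region                 betweenness normalized_betweenness is_hub
#>   <chr>                        <dbl>                  <dbl> <lgl>
#> 1 lh_insula                    1031.                  14.0  TRUE
#> 2 lh_bankssts                   925.                  12.6  TRUE
#> 3 lh_medialorbitofrontal        635.                   8.65 TRUE

perm <- permutation_test_auc(cohort, c("e_glob", "e_loc", "q"),
                             grid = density_grid(0.05, 0.40, 0.05),
                             n_perm = 200, seed = 2)
tidy(perm)
#> # A tibble: 3 x 7
#>   statistic  observed_a observed_b observed_diff p_two_tailed n_perm  seed
#>   <chr>           <dbl>      <dbl>         <dbl>        <dbl>  <dbl> <dbl>
#> 1 auc_e_glob      0.156      0.187       -0.0307       0.0498    200     2
#> 2 auc_e_loc       0.284      0.249        0.0348       0.0249    200     2
#> 3 auc_q           0.212      0.161        0.0506       0.0199    200     2
```

The HC group's planted connectors (regions 1 and 34, `lh_bankssts` and
`lh_insula`) are recovered as its two strongest hubs, and `sigma > 1`
confirms small-world organisation. The patient-spec group
(`r_within = 0.35` vs 0.5) loses local efficiency and modularity AUC —
its weaker within-module covariance lets more between-module edges
survive thresholding — and for the same reason gains some global
efficiency at matched density; all three differences are flagged by the
permutation test at `p < 0.05` (raw). `run_pipeline(run_config(...))`
performs all of the above plus robustness curves and writes a run
directory with TSV/JSON outputs and a manifest that reproduces the run
byte for byte.

A command-line wrapper is provided at `inst/scripts/covnet.R`
(`covnet.R simulate ...` and `covnet.R run ...`).

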