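# Subject-relabelling permutation tests. The null distribution is built by
# randomly reassigning subjects to the two groups (preserving the original
# group sizes) and recomputing the entire pipeline — correlation matrix,
# thresholding, metric, AUC — for each relabelling.

new_permutation_result <- function(statistic_name, observed_a, observed_b,
                                   null_diffs, n_perm, seed) {
  observed_diff <- observed_a - observed_b
  p <- (1 + sum(abs(null_diffs) >= abs(observed_diff))) / (n_perm + 1)
  structure(
    list(
      statistic_name = statistic_name,
      observed_a = observed_a, observed_b = observed_b,
      observed_diff = observed_diff,
      null_diffs = null_diffs,
      p_two_tailed = p, n_perm = n_perm, seed = seed
    ),
    class = "covnet_permutation"
  )
}

#' @export
print.covnet_permutation <- function(x, ...) {
  cat(sprintf(
    "<covnet_permutation> %s: diff (A - B) = %.4f, p = %.4f (%d permutations)\n",
    x$statistic_name, x$observed_diff, x$p_two_tailed, x$n_perm
  ))
  invisible(x)
}

#' @method tidy covnet_permutation
#' @export
tidy.covnet_permutation <- function(x, ...) {
  tibble(
    statistic = x$statistic_name,
    observed_a = x$observed_a, observed_b = x$observed_b,
    observed_diff = x$observed_diff,
    p_two_tailed = x$p_two_tailed,
    n_perm = x$n_perm, seed = x$seed
  )
}

#' @method tidy covnet_permutation_set
#' @export
tidy.covnet_permutation_set <- function(x, ...) {
  dplyr::bind_rows(lapply(x, tidy))
}

#' @export
print.covnet_permutation_set <- function(x, ...) {
  cat(sprintf("<covnet_permutation_set> %d statistics\n", length(x)))
  print(tidy(x))
  invisible(x)
}

# Relabelled group-size-preserving index sets for each permutation.
permuted_labels <- function(n_total, n_a, n_perm, seed) {
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_perm), function(i) sample.int(n_total, n_a))
  })
}

#' Permutation test on AUC group differences
#'
#' Compares the area under the metric-versus-density curve between the two
#' groups of a cohort. The observed difference (group A minus group B,
#' groups ordered by first appearance) is referred to a null distribution
#' of `n_perm` subject relabellings that preserve the original group sizes;
#' the full pipeline is recomputed per relabelling. The two-tailed p-value
#' uses the add-one rule `(1 + #{|null| >= |observed|}) / (n_perm + 1)`, so
#' p is never exactly zero.
#'
#' Several metrics can be tested in one call; the thresholded networks of
#' each relabelling are shared across metrics, which is both faster and
#' exactly what a full-pipeline permutation implies. Densities where a
#' metric is undefined in either group are dropped pairwise from both AUCs
#' of that comparison.
#'
#' @param cohort Cohort tibble with exactly two groups.
#' @param metrics Character vector of metrics (see [metric_profile()]).
#' @param grid Density grid.
#' @param n_perm Number of relabellings (default 1000).
#' @param seed Integer seed; observed-profile null ensembles and each
#'   permutation get independent derived seeds.
#' @param n_nulls,n_swaps_per_edge Null-ensemble settings for
#'   gamma/lambda/sigma.
#' @param n_restarts Modularity restarts for `q`.
#' @return A single `covnet_permutation` when one metric is requested,
#'   otherwise a named `covnet_permutation_set` (use [tidy()] for a
#'   one-row-per-metric tibble).
#' @export
#' @examples
#' specs <- default_cohort_specs(n_regions = 10)
#' cohort <- generate_cohort(specs$control, specs$patient, 15, 15, seed = 1)
#' pt <- permutation_test_auc(cohort, "e_glob",
#'                            grid = density_grid(0.1, 0.4, 0.1),
#'                            n_perm = 50, seed = 1)
#' tidy(pt)
permutation_test_auc <- function(cohort, metrics = "e_glob",
                                 grid = density_grid(), n_perm = 1000,
                                 seed = 1, n_nulls = 100,
                                 n_swaps_per_edge = 10, n_restarts = 20) {
  validate_cohort(cohort)
  metrics <- match.arg(metrics, covnet_metrics, several.ok = TRUE)
  if (n_perm < 100) abort("n_perm must be at least 100")
  groups <- group_levels(cohort)
  regions <- region_columns(cohort)
  all_vals <- as.matrix(cohort[, regions, drop = FALSE])
  storage.mode(all_vals) <- "double"
  idx_a <- which(cohort$group == groups[1])
  n_a <- length(idx_a)
  n_total <- nrow(cohort)

  seeds <- derive_seeds(seed, 2L + n_perm)
  run_pair <- function(rows_a, seed_pair) {
    rows_b <- setdiff(seq_len(n_total), rows_a)
    pa <- profile_engine(all_vals[rows_a, , drop = FALSE], grid, metrics,
                         n_nulls = n_nulls,
                         n_swaps_per_edge = n_swaps_per_edge,
                         n_restarts = n_restarts, seed = seed_pair[1])
    pb <- profile_engine(all_vals[rows_b, , drop = FALSE], grid, metrics,
                         n_nulls = n_nulls,
                         n_swaps_per_edge = n_swaps_per_edge,
                         n_restarts = n_restarts, seed = seed_pair[2])
    # pairwise drop: a density counts only if defined in both groups
    vapply(metrics, function(m) {
      c(a = auc_trapezoid(grid, pa[m, ], drop_with = pb[m, ]),
        b = auc_trapezoid(grid, pb[m, ], drop_with = pa[m, ]))
    }, numeric(2))
  }

  observed <- run_pair(idx_a, seeds[1:2])
  perms <- permuted_labels(n_total, n_a, n_perm, seed = seeds[3])
  null_diffs <- matrix(NA_real_, n_perm, length(metrics),
                       dimnames = list(NULL, metrics))
  perm_seeds <- derive_seeds(seeds[3], 2L * n_perm)
  for (pi in seq_len(n_perm)) {
    aucs <- run_pair(perms[[pi]], perm_seeds[c(2 * pi - 1, 2 * pi)])
    null_diffs[pi, ] <- aucs["a", ] - aucs["b", ]
  }

  results <- lapply(metrics, function(m) {
    new_permutation_result(
      statistic_name = paste0("auc_", m),
      observed_a = observed["a", m], observed_b = observed["b", m],
      null_diffs = null_diffs[, m], n_perm = n_perm, seed = seed
    )
  })
  names(results) <- metrics
  if (length(results) == 1L) return(results[[1]])
  structure(results, class = "covnet_permutation_set")
}

#' Permutation test on a scalar network statistic
#'
#' Applies the same group-size-preserving subject-relabelling scheme to any
#' scalar statistic of the form `function(cohort, group) -> number`, e.g. a
#' region's normalised betweenness or the largest-component size after an
#' attack, both conventionally evaluated on networks thresholded at a fixed
#' density (19% by default in the factories below).
#'
#' @param cohort Cohort tibble with exactly two groups.
#' @param statistic Function of `(cohort, group)` returning a finite
#'   scalar.
#' @param n_perm Number of relabellings (default 1000).
#' @param seed Integer seed.
#' @param statistic_name Label for reporting.
#' @return A `covnet_permutation`.
#' @seealso [hub_betweenness_statistic()], [attack_robustness_statistic()]
#' @export
permutation_test_scalar <- function(cohort, statistic, n_perm = 1000,
                                    seed = 1,
                                    statistic_name = "scalar") {
  validate_cohort(cohort)
  groups <- group_levels(cohort)
  idx_a <- which(cohort$group == groups[1])
  n_total <- nrow(cohort)

  eval_pair <- function(rows_a, perm_index) {
    relabeled <- cohort
    relabeled$group <- groups[2]
    relabeled$group[rows_a] <- groups[1]
    vals <- c(statistic(relabeled, groups[1]), statistic(relabeled, groups[2]))
    if (any(!is.finite(vals))) {
      abort(sprintf("statistic returned a non-finite value at permutation %d",
                    perm_index))
    }
    vals[1] - vals[2]
  }

  observed_a <- statistic(cohort, groups[1])
  observed_b <- statistic(cohort, groups[2])
  if (!is.finite(observed_a) || !is.finite(observed_b)) {
    abort("statistic returned a non-finite value on the observed groups")
  }
  perms <- permuted_labels(n_total, length(idx_a), n_perm, seed = seed)
  null_diffs <- vapply(seq_len(n_perm),
                       function(pi) eval_pair(perms[[pi]], pi), numeric(1))
  new_permutation_result(statistic_name, observed_a, observed_b,
                         null_diffs, n_perm, seed)
}

#' Scalar-statistic factories for fixed-density comparisons
#'
#' `hub_betweenness_statistic()` returns a statistic giving a region's
#' normalised betweenness (betweenness over network-mean betweenness) in
#' the group network thresholded at `density`; use it with
#' [permutation_test_scalar()] to test per-hub group differences.
#' `attack_robustness_statistic()` returns the relative size of the
#' largest connected component after removing `fraction` of the nodes or
#' edges, either by targeted attack or (seeded) random failure.
#'
#' @param region Region name.
#' @param density Fixed network density (default 0.19).
#' @param mode `"node"` or `"edge"`.
#' @param fraction Removal fraction at which to read the curve.
#' @param type `"targeted"` or `"random"`.
#' @param n_reps,seed Settings for the random-failure variant.
#' @return A function of `(cohort, group)` returning a scalar.
#' @export
hub_betweenness_statistic <- function(region, density = 0.19) {
  force(region); force(density)
  function(cohort, group) {
    net <- threshold_at_density(correlation_matrix(cohort, group), density)
    tab <- node_betweenness(net)
    if (!region %in% tab$region) abort(sprintf("unknown region '%s'", region))
    mb <- mean(tab$betweenness)
    if (mb == 0) return(NaN)
    tab$betweenness[tab$region == region] / mb
  }
}

#' @rdname hub_betweenness_statistic
#' @export
attack_robustness_statistic <- function(mode = c("node", "edge"),
                                        fraction = 0.2, density = 0.19,
                                        type = c("targeted", "random"),
                                        n_reps = 100, seed = 1) {
  mode <- match.arg(mode)
  type <- match.arg(type)
  force(fraction); force(density); force(n_reps); force(seed)
  function(cohort, group) {
    net <- threshold_at_density(correlation_matrix(cohort, group), density)
    curve <- if (type == "targeted") {
      targeted_attack_curve(net, mode, fractions = c(0, fraction))
    } else {
      random_failure_curve(net, mode, n_reps = n_reps, seed = seed,
                           fractions = c(0, fraction))
    }
    curve$relative_size[2]
  }
}

#' Bonferroni adjustment
#'
#' Multiplies each p-value by the family size `m` and caps at 1.
#'
#' @param p_values Vector of p-values in (0, 1].
#' @param m Family size; at least `length(p_values)`.
#' @return Adjusted p-values, same order.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (any(p_values <= 0 | p_values > 1)) abort("p-values must lie in (0, 1]")
  if (m < length(p_values)) abort("m must be at least length(p_values)")
  stats::p.adjust(p_values, method = "bonferroni", n = m)
}
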