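# Metric-versus-density profiles. The engine below is the shared core of
# metric_profile() and the permutation tests: given one group's
# subject x region values it computes the correlation matrix once, ranks
# the positive correlations once, and evaluates the requested metrics on
# the nested edge-set prefixes across the density grid.

covnet_metrics <- c("cp", "lp", "gamma", "lambda", "sigma",
                    "e_glob", "e_loc", "q")

# values: subject x region matrix for one group.
# Returns a metrics x densities numeric matrix (NA where undefined).
profile_engine <- function(values, grid, metrics,
                           n_nulls = 100, n_swaps_per_edge = 10,
                           n_restarts = 20, seed = 1) {
  metrics <- match.arg(metrics, covnet_metrics, several.ok = TRUE)
  r <- stats::cor(values)
  n <- ncol(values)
  ranked <- ranked_positive_edges(r)
  need_null <- any(metrics %in% c("gamma", "lambda", "sigma"))
  need_q <- "q" %in% metrics
  seeds <- derive_seeds(seed, 2L * length(grid))

  out <- matrix(NA_real_, length(metrics), length(grid),
                dimnames = list(metrics, format(grid)))
  for (di in seq_along(grid)) {
    e_target <- min(round(grid[di] * n * (n - 1) / 2), nrow(ranked))
    if (e_target == 0) next
    sel <- ranked[seq_len(e_target), c("i", "j"), drop = FALSE]
    adj <- matrix(0L, n, n,
                  dimnames = list(colnames(values), colnames(values)))
    adj[sel] <- 1L
    adj[sel[, 2:1, drop = FALSE]] <- 1L
    net <- new_binary_network(adj, colnames(values), grid[di])

    if (need_null) {
      # a degenerate null ensemble (e.g. zero clustering in every null at
      # very low density) leaves the coefficients undefined at this density
      sw <- tryCatch(
        small_world_params(net, n_nulls = n_nulls, seed = seeds[di],
                           n_swaps_per_edge = n_swaps_per_edge),
        error = function(e) list(gamma = NA_real_, lambda = NA_real_,
                                 sigma = NA_real_)
      )
    }
    for (m in metrics) {
      out[m, di] <- switch(
        m,
        cp = clustering_coefficient(net),
        lp = characteristic_path_length(net),
        gamma = sw$gamma,
        lambda = sw$lambda,
        sigma = sw$sigma,
        e_glob = global_efficiency(net),
        e_loc = local_efficiency(net),
        q = network_modularity(net, seed = seeds[length(grid) + di],
                               n_restarts = n_restarts)$q
      )
    }
  }
  out
}

#' Metric profile of one group across the density grid
#'
#' Runs the full construction chain for one group — correlation matrix,
#' density thresholding, metric evaluation — at every grid density, and
#' summarises the curve by its trapezoidal area under the curve (AUC), the
#' threshold-free quantity used for group comparison.
#'
#' @param cohort Cohort tibble.
#' @param group Group label.
#' @param metric One of `"cp"`, `"lp"`, `"gamma"`, `"lambda"`, `"sigma"`,
#'   `"e_glob"`, `"e_loc"`, `"q"`.
#' @param grid Densities from [density_grid()].
#' @param n_nulls Null-ensemble size for gamma/lambda/sigma (default 100).
#' @param n_swaps_per_edge Rewiring intensity for the null ensemble.
#' @param n_restarts Modularity restarts for `q`.
#' @param seed Integer seed (null ensembles and modularity heuristic).
#' @return A tibble of class `covnet_profile` with columns `density` and
#'   `value`; attributes `metric`, `group` and `auc`. Densities where the
#'   metric is undefined are recorded as `NA` and excluded from the AUC
#'   with a warning.
#' @export
#' @examples
#' specs <- default_cohort_specs(n_regions = 12)
#' cohort <- generate_cohort(specs$control, specs$patient, 25, 25, seed = 1)
#' prof <- metric_profile(cohort, "A", "e_glob",
#'                        grid = density_grid(0.1, 0.4, 0.1))
#' glance(prof)
metric_profile <- function(cohort, group, metric, grid = density_grid(),
                           n_nulls = 100, n_swaps_per_edge = 10,
                           n_restarts = 20, seed = 1) {
  validate_cohort(cohort)
  metric <- match.arg(metric, covnet_metrics)
  vals <- group_values(cohort, group)
  prof <- profile_engine(vals, grid, metric, n_nulls = n_nulls,
                         n_swaps_per_edge = n_swaps_per_edge,
                         n_restarts = n_restarts, seed = seed)[1, ]
  if (anyNA(prof)) {
    warn(sprintf("metric '%s' undefined at %d grid densities; excluded from AUC",
                 metric, sum(is.na(prof))))
  }
  auc <- unname(auc_trapezoid(grid, prof))
  structure(
    tibble(density = grid, value = unname(prof)),
    class = c("covnet_profile", class(tibble())),
    metric = metric, group = group, auc = auc
  )
}

#' @export
print.covnet_profile <- function(x, ...) {
  cat(sprintf("<covnet_profile> metric '%s', group '%s', AUC = %.4f\n",
              attr(x, "metric"), attr(x, "group"), attr(x, "auc")))
  NextMethod()
}

#' @method glance covnet_profile
#' @export
glance.covnet_profile <- function(x, ...) {
  tibble(
    metric = attr(x, "metric"), group = attr(x, "group"),
    auc = attr(x, "auc"),
    n_densities = nrow(x), n_defined = sum(is.finite(x$value))
  )
}
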