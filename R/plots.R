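# ggplot2 methods for the package's result types.

#' Plot a metric density profile
#'
#' @param object A `covnet_profile` from [metric_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot covnet_profile
#' @export
autoplot.covnet_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$density, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = "network density", y = attr(object, "metric"),
      title = sprintf("%s profile, group %s (AUC = %.3f)",
                      attr(object, "metric"), attr(object, "group"),
                      attr(object, "auc"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a robustness curve
#'
#' @param object A `covnet_robustness` from [random_failure_curve()] or
#'   [targeted_attack_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot covnet_robustness
#' @export
autoplot.covnet_robustness <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction,
                                        y = .data$relative_size)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "fraction removed", y = "relative size of largest component",
      title = attr(object, "mode")
    ) +
    ggplot2::theme_minimal()
  if ("sd" %in% names(df)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = pmax(.data$relative_size - .data$sd, 0),
                   ymax = pmin(.data$relative_size + .data$sd, 1)),
      alpha = 0.2
    )
  }
  p
}

#' Plot a permutation null distribution
#'
#' Histogram of the permutation null differences with the observed
#' difference marked.
#'
#' @param object A `covnet_permutation`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot covnet_permutation
#' @export
autoplot.covnet_permutation <- function(object, ...) {
  ggplot2::ggplot(tibble(null_diff = object$null_diffs),
                  ggplot2::aes(x = .data$null_diff)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_diff,
                        colour = "red", linewidth = 0.8) +
    ggplot2::labs(
      x = "null difference (A - B)", y = "count",
      title = sprintf("%s: observed = %.4f, p = %.4f",
                      object$statistic_name, object$observed_diff,
                      object$p_two_tailed)
    ) +
    ggplot2::theme_minimal()
}
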