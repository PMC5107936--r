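#' Group-level inter-regional correlation matrix
#'
#' Computes the Pearson (product-moment) correlation between every pair of
#' region columns across the subjects of one group. This is the structural
#' covariance matrix R whose positive entries are later thresholded into a
#' binary network; the diagonal is ignored by all consumers.
#'
#' @param cohort Cohort tibble (`subject`, `group`, region columns).
#' @param group Group label to subset to (must have >= 3 subjects).
#' @return An object of class `covnet_correlation`: a list with elements
#'   `r` (symmetric region-by-region matrix), `regions`, `n_subjects` and
#'   `group`.
#' @export
#' @examples
#' specs <- default_cohort_specs(n_regions = 10)
#' cohort <- generate_cohort(specs$control, specs$patient, 20, 20, seed = 1)
#' cm <- correlation_matrix(cohort, "A")
#' cm
correlation_matrix <- function(cohort, group) {
  vals <- group_values(cohort, group)
  if (nrow(vals) < 3L) {
    abort(sprintf("group '%s' has fewer than 3 subjects", group))
  }
  sds <- apply(vals, 2, stats::sd)
  if (any(sds == 0)) {
    abort(sprintf("region '%s' has zero variance within group '%s'",
                  colnames(vals)[sds == 0][1], group))
  }
  structure(
    list(r = stats::cor(vals), regions = colnames(vals),
         n_subjects = nrow(vals), group = group),
    class = "covnet_correlation"
  )
}

#' @export
print.covnet_correlation <- function(x, ...) {
  cat(sprintf("<covnet_correlation> %d regions, group '%s' (n = %d)\n",
              length(x$regions), x$group, x$n_subjects))
  off <- x$r[upper.tri(x$r)]
  cat(sprintf("  off-diagonal r: min %.3f, median %.3f, max %.3f\n",
              min(off), stats::median(off), max(off)))
  invisible(x)
}

#' @method tidy covnet_correlation
#' @export
tidy.covnet_correlation <- function(x, ...) {
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble(
    region_a = x$regions[idx[, 1]],
    region_b = x$regions[idx[, 2]],
    r = x$r[idx]
  )
}

#' Write a correlation matrix as TSV
#'
#' Square layout with region names as both header row and first column.
#'
#' @param x A `covnet_correlation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_correlation <- function(x, path) {
  stopifnot(inherits(x, "covnet_correlation"))
  df <- as.data.frame(x$r)
  df <- cbind(region = x$regions, df)
  readr::write_tsv(df, path)
  invisible(path)
}
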