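#' Generate a two-group synthetic cohort
#'
#' Draws subject-by-region thickness values for two groups from multivariate
#' normal distributions whose correlation structure is given by each group's
#' [covariance_spec()], scaled by the per-region standard deviations and
#' shifted by the per-region means. Group differences are expressed through
#' the covariance structure (e.g. a lower within-module correlation in the
#' patient spec), not through mean shifts, because every downstream network
#' statistic is correlation-based.
#'
#' @param spec_a,spec_b Covariance specs for the two groups; must agree on
#'   region count and ordering.
#' @param n_a,n_b Number of subjects per group (>= 3).
#' @param seed Integer seed; the call is fully reproducible under it and
#'   leaves the global RNG state untouched.
#' @param group_names Length-2 character vector of group labels.
#' @return A tibble with columns `subject`, `group`, then one numeric column
#'   per region (values in mm). Group A rows come first.
#' @export
#' @examples
#' specs <- default_cohort_specs()
#' cohort <- generate_cohort(specs$control, specs$patient, 10, 10, seed = 1)
#' dim(cohort)
generate_cohort <- function(spec_a, spec_b, n_a, n_b, seed,
                            group_names = c("A", "B")) {
  stopifnot(inherits(spec_a, "covnet_spec"), inherits(spec_b, "covnet_spec"))
  if (spec_a$n_regions != spec_b$n_regions ||
      !identical(spec_a$region_names, spec_b$region_names)) {
    abort("spec_a and spec_b must have identical regions in the same order")
  }
  if (n_a < 3 || n_b < 3) abort("each group needs at least 3 subjects")
  if (length(group_names) != 2L || anyDuplicated(group_names)) {
    abort("group_names must be two distinct labels")
  }

  draw <- function(spec, n) {
    r <- build_covariance(spec)
    sigma <- r * tcrossprod(spec$sd_thickness)
    MASS::mvrnorm(n, mu = spec$mean_thickness, Sigma = sigma)
  }
  vals <- withr::with_seed(as.integer(seed), {
    a <- draw(spec_a, n_a)
    b <- draw(spec_b, n_b)
    rbind(a, b)
  })
  colnames(vals) <- spec_a$region_names
  out <- tibble(
    subject = sprintf("sub_%03d", seq_len(n_a + n_b)),
    group = rep(group_names, c(n_a, n_b))
  )
  dplyr::bind_cols(out, as_tibble(vals))
}

#' Default synthetic study conditions
#'
#' Returns the pair of covariance specs used as the package's reference
#' study: 68 Desikan-Killiany regions in 4 planted modules, a control group
#' with within-module correlation 0.5 and two planted cross-module connector
#' (hub) regions, and a patient group with within-module correlation lowered
#' to 0.35 and a partly different hub set — mirroring a cohort in which the
#' clinical group shows weaker covariance segregation and relocated hubs.
#'
#' @param n_regions Number of regions (default 68).
#' @param n_modules Number of planted modules (default 4).
#' @param r_within_control,r_within_patient Within-module correlations.
#' @param r_between Between-module correlation shared by both groups.
#' @param r_hub Cross-module correlation of planted hub regions.
#' @return A list with elements `control` and `patient`, each a
#'   [covariance_spec()].
#' @export
default_cohort_specs <- function(n_regions = 68, n_modules = 4,
                                 r_within_control = 0.5,
                                 r_within_patient = 0.35,
                                 r_between = 0.1, r_hub = 0.35) {
  hub_ctrl <- c(1L, ceiling(n_regions / 2))
  hub_pat <- c(ceiling(n_regions / 4), n_regions)
  list(
    control = covariance_spec(
      n_regions, partition = n_modules, r_within = r_within_control,
      r_between = r_between, hub_regions = hub_ctrl, r_hub = r_hub
    ),
    patient = covariance_spec(
      n_regions, partition = n_modules, r_within = r_within_patient,
      r_between = r_between, hub_regions = hub_pat, r_hub = r_hub
    )
  )
}

validate_cohort <- function(cohort, group_col = "group",
                            subject_col = "subject") {
  if (!all(c(subject_col, group_col) %in% names(cohort))) {
    abort(sprintf("cohort must have '%s' and '%s' columns",
                  subject_col, group_col))
  }
  regions <- region_columns(cohort, group_col, subject_col)
  if (length(regions) < 2L) abort("cohort needs at least 2 region columns")
  if (anyDuplicated(cohort[[subject_col]])) {
    dup <- cohort[[subject_col]][duplicated(cohort[[subject_col]])][1]
    abort(sprintf("duplicated subject ID: '%s'", dup))
  }
  groups <- unique(as.character(cohort[[group_col]]))
  if (length(groups) != 2L) {
    abort(sprintf("cohort must contain exactly 2 groups, found %d",
                  length(groups)))
  }
  for (rc in regions) {
    col <- cohort[[rc]]
    if (!is.numeric(col)) {
      abort(sprintf("region column '%s' is not numeric", rc))
    }
    if (anyNA(col)) {
      abort(sprintf("missing values in region column '%s' (row %d)",
                    rc, which(is.na(col))[1]))
    }
    if (stats::var(col) == 0) {
      abort(sprintf("region column '%s' has zero variance", rc))
    }
  }
  invisible(cohort)
}

#' Write / read a cohort table as CSV
#'
#' The on-disk format is a plain UTF-8 CSV with header
#' `subject,group,<region names...>`, one row per subject, `.` decimal
#' separator and no index column. `read_cohort()` validates the table on
#' load: numeric region columns, no missing values, unique subject IDs and
#' exactly two groups.
#'
#' @param cohort A cohort tibble as produced by [generate_cohort()].
#' @param path File path.
#' @param group_col Name of the group-label column (default `"group"`).
#' @return `read_cohort()` returns a validated tibble; `write_cohort()`
#'   returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  readr::write_csv(cohort, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, group_col = "group") {
  cohort <- readr::read_csv(path, show_col_types = FALSE,
                            progress = FALSE)
  if (group_col != "group") {
    names(cohort)[names(cohort) == group_col] <- "group"
  }
  validate_cohort(cohort)
  cohort
}
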