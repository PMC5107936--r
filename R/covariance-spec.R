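#' Specify a planted covariance structure for a synthetic cohort
#'
#' A covariance spec describes the region-level correlation structure one
#' group of a synthetic cohort is drawn from: a partition of regions into
#' modules with correlation `r_within` inside a module and `r_between`
#' across modules, plus optional hub regions whose cross-module correlation
#' is raised to `r_hub` so they act as connectors in the thresholded
#' network. Per-region means and standard deviations (in mm) set the scale
#' of the simulated thickness values.
#'
#' @param n_regions Number of regions (nodes).
#' @param partition Integer or character vector of length `n_regions` giving
#'   each region's module, or a single integer number of modules to split
#'   the regions into contiguous, near-equal blocks.
#' @param r_within Target correlation between regions of the same module,
#'   in `[0, 1)`.
#' @param r_between Target correlation between regions of different
#'   modules, in `[0, r_within]` (strictly below `r_within` when positive).
#' @param hub_regions Integer indices (1-based) of regions given elevated
#'   cross-module correlation `r_hub`.
#' @param r_hub Correlation between a hub region and regions outside its
#'   module, in `(r_between, 1)`. Required when `hub_regions` is non-empty.
#' @param mean_thickness Per-region mean thickness in mm (recycled).
#' @param sd_thickness Per-region standard deviation in mm (recycled,
#'   must be > 0).
#' @param region_names Optional region names; defaults to `region_01`, ...
#'   (or [dk68_regions()] when `n_regions == 68`).
#'
#' @return An object of class `covnet_spec`.
#' @seealso [build_covariance()], [generate_cohort()]
#' @export
#' @examples
#' spec <- covariance_spec(6, partition = 3, r_within = 0.6, r_between = 0.1,
#'                         hub_regions = 1, r_hub = 0.4)
#' build_covariance(spec)
covariance_spec <- function(n_regions, partition, r_within, r_between,
                            hub_regions = integer(), r_hub = NULL,
                            mean_thickness = 2.5, sd_thickness = 0.25,
                            region_names = NULL) {
  n_regions <- as.integer(n_regions)
  if (n_regions < 2L) abort("n_regions must be at least 2")
  if (length(partition) == 1L && is.numeric(partition)) {
    k <- as.integer(partition)
    partition <- sort(rep_len(seq_len(k), n_regions))
  }
  if (length(partition) != n_regions) {
    abort("partition must label every region exactly once")
  }
  partition <- as.integer(factor(partition, levels = unique(partition)))
  if (!(r_within >= 0 && r_within < 1)) abort("r_within must lie in [0, 1)")
  if (r_between < 0 || (r_between > r_within) ||
      (r_between == r_within && r_between > 0)) {
    abort("r_between must lie in [0, r_within)")
  }
  hub_regions <- as.integer(hub_regions)
  if (length(hub_regions)) {
    if (any(hub_regions < 1L | hub_regions > n_regions)) {
      abort("hub_regions indices out of range")
    }
    if (is.null(r_hub)) abort("r_hub required when hub_regions is non-empty")
    if (!(r_hub > r_between && r_hub < 1)) {
      abort("r_hub must lie in (r_between, 1)")
    }
  }
  mean_thickness <- rep_len(mean_thickness, n_regions)
  sd_thickness <- rep_len(sd_thickness, n_regions)
  if (any(sd_thickness <= 0)) abort("sd_thickness must be positive")
  if (is.null(region_names)) {
    region_names <- if (n_regions == 68L) dk68_regions() else
      sprintf("region_%02d", seq_len(n_regions))
  }
  if (anyDuplicated(region_names)) abort("region names must be unique")
  structure(
    list(
      n_regions = n_regions, partition = partition,
      r_within = r_within, r_between = r_between,
      hub_regions = hub_regions, r_hub = r_hub,
      mean_thickness = mean_thickness, sd_thickness = sd_thickness,
      region_names = region_names
    ),
    class = "covnet_spec"
  )
}

#' @export
print.covnet_spec <- function(x, ...) {
  cat(sprintf(
    "<covnet_spec> %d regions, %d modules, r_within=%.2f, r_between=%.2f",
    x$n_regions, length(unique(x$partition)), x$r_within, x$r_between
  ))
  if (length(x$hub_regions)) {
    cat(sprintf(", %d hub region(s) at r_hub=%.2f",
                length(x$hub_regions), x$r_hub))
  }
  cat("\n")
  invisible(x)
}

#' Build the region-by-region correlation matrix implied by a spec
#'
#' Constructs the target correlation matrix entry by entry — `r_within`
#' inside a module, `r_hub` when either region is a hub and the pair spans
#' modules, `r_between` otherwise, unit diagonal — and repairs it to
#' positive semi-definiteness if needed by clipping negative eigenvalues to
#' zero, reconstructing, and renormalising the diagonal. The repair must
#' move no entry by more than `repair_tol` from its target.
#'
#' @param spec A [covariance_spec()].
#' @param repair_tol Maximum allowed absolute deviation of any entry from
#'   its target after PSD repair (default 0.05).
#' @return A symmetric positive semi-definite correlation matrix with unit
#'   diagonal and region names on both dimensions.
#' @export
build_covariance <- function(spec, repair_tol = 0.05) {
  stopifnot(inherits(spec, "covnet_spec"))
  n <- spec$n_regions
  same_module <- outer(spec$partition, spec$partition, "==")
  target <- ifelse(same_module, spec$r_within, spec$r_between)
  if (length(spec$hub_regions)) {
    is_hub <- seq_len(n) %in% spec$hub_regions
    hub_pair <- outer(is_hub, is_hub, "|") & !same_module
    target[hub_pair] <- spec$r_hub
  }
  diag(target) <- 1
  dimnames(target) <- list(spec$region_names, spec$region_names)

  eig <- eigen(target, symmetric = TRUE)
  if (min(eig$values) >= -1e-10) {
    return(target)
  }
  vals <- pmax(eig$values, 0)
  rep_mat <- eig$vectors %*% (vals * t(eig$vectors))
  d <- sqrt(diag(rep_mat))
  rep_mat <- rep_mat / tcrossprod(d)
  diag(rep_mat) <- 1
  dev <- abs(rep_mat - target)
  if (max(dev) > repair_tol) {
    worst <- which(dev == max(dev), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "PSD repair moved entry (%s, %s) by %.4f, beyond tolerance %.3f",
      spec$region_names[worst[1]], spec$region_names[worst[2]],
      max(dev), repair_tol
    ))
  }
  dimnames(rep_mat) <- dimnames(target)
  rep_mat
}
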