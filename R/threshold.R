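#' Density grid for network thresholding
#'
#' The density (wiring-cost) grid over which binary networks are built and
#' metric profiles integrated. The default mirrors the common connectomics
#' range: 5% to 40% in steps of 1%, chosen low enough to suppress spurious
#' edges and high enough for small-world estimation to be stable.
#'
#' @param d_min,d_max Grid endpoints (fractions in (0, 1]).
#' @param step Grid spacing; `d_max` must be reachable from `d_min` in an
#'   integer number of steps and is included.
#' @return A strictly increasing numeric vector of densities.
#' @export
#' @examples
#' length(density_grid()) # 36 points
density_grid <- function(d_min = 0.05, d_max = 0.40, step = 0.01) {
  if (!(d_min > 0 && d_max <= 1 && d_min <= d_max)) {
    abort("need 0 < d_min <= d_max <= 1")
  }
  if (step <= 0) abort("step must be positive")
  n <- round((d_max - d_min) / step)
  if (abs(d_min + n * step - d_max) > 1e-9) {
    abort("d_max must be d_min plus an integer number of steps")
  }
  round(d_min + step * (0:n), 10)
}

# Upper-triangle positive entries of a correlation matrix, ordered by
# decreasing value with deterministic tie-breaks (smaller row, then smaller
# column index). Returns a matrix with columns i, j, r.
ranked_positive_edges <- function(r) {
  idx <- which(upper.tri(r), arr.ind = TRUE)
  vals <- r[idx]
  pos <- vals > 0
  idx <- idx[pos, , drop = FALSE]
  vals <- vals[pos]
  ord <- order(-vals, idx[, 1], idx[, 2])
  cbind(i = idx[ord, 1], j = idx[ord, 2], r = vals[ord])
}

new_binary_network <- function(adjacency, regions, target_density,
                               truncated = FALSE) {
  n <- nrow(adjacency)
  k <- sum(adjacency)
  structure(
    list(
      adjacency = adjacency, regions = regions,
      density = k / (n * (n - 1)), k_nonzero = k,
      target_density = target_density, truncated = truncated
    ),
    class = "covnet_network"
  )
}

#' Threshold a correlation matrix into a binary network at a given density
#'
#' Retains exactly the `E = round(density * N * (N - 1) / 2)` strongest
#' strictly positive off-diagonal correlations as undirected, unweighted
#' edges. Density follows the convention `K / (N * (N - 1))` with `K`
#' counting both symmetric adjacency entries, so the achieved density is
#' recomputed from the retained edges. Negative and zero correlations are
#' never admitted: if fewer than `E` positive correlations exist, the
#' network is returned at the achievable density with a warning and its
#' `truncated` flag set.
#'
#' Ties at the threshold are broken deterministically by (smaller row
#' index, smaller column index), so thresholding is reproducible and edge
#' sets are nested across densities.
#'
#' @param r A `covnet_correlation` or a plain symmetric correlation matrix.
#' @param density Target density in (0, 1].
#' @return An object of class `covnet_network` with elements `adjacency`
#'   (symmetric 0/1 matrix, zero diagonal), `regions`, `density` (achieved),
#'   `k_nonzero`, `target_density` and `truncated`.
#' @export
#' @examples
#' specs <- default_cohort_specs(n_regions = 10)
#' cohort <- generate_cohort(specs$control, specs$patient, 30, 30, seed = 1)
#' net <- cohort |> correlation_matrix("A") |> threshold_at_density(0.19)
#' net$k_nonzero
threshold_at_density <- function(r, density) {
  if (!(density > 0 && density <= 1)) abort("density must lie in (0, 1]")
  if (inherits(r, "covnet_correlation")) {
    regions <- r$regions
    r <- r$r
  } else {
    regions <- rownames(r) %||% sprintf("region_%02d", seq_len(nrow(r)))
  }
  n <- nrow(r)
  e_target <- round(density * n * (n - 1) / 2)
  ranked <- ranked_positive_edges(r)
  truncated <- nrow(ranked) < e_target
  if (truncated) {
    warn(sprintf(
      "only %d positive correlations available for %d requested edges; achieved density %.4f",
      nrow(ranked), e_target, 2 * nrow(ranked) / (n * (n - 1))
    ))
  }
  take <- min(e_target, nrow(ranked))
  adj <- matrix(0L, n, n, dimnames = list(regions, regions))
  if (take > 0) {
    sel <- ranked[seq_len(take), , drop = FALSE]
    adj[sel[, c("i", "j"), drop = FALSE]] <- 1L
    adj[sel[, c("j", "i"), drop = FALSE]] <- 1L
  }
  new_binary_network(adj, regions, density, truncated)
}

#' Threshold a correlation matrix across a density grid
#'
#' One binary network per grid density, sharing a single deterministic edge
#' ranking so that the edge set at a lower density is a subset of the edge
#' set at any higher density.
#'
#' @param r A `covnet_correlation` or symmetric correlation matrix.
#' @param grid Densities from [density_grid()].
#' @return A named list of `covnet_network` objects (names are densities).
#' @export
binarize_over_grid <- function(r, grid = density_grid()) {
  if (inherits(r, "covnet_correlation")) {
    regions <- r$regions
    r <- r$r
  } else {
    regions <- rownames(r) %||% sprintf("region_%02d", seq_len(nrow(r)))
  }
  n <- nrow(r)
  ranked <- ranked_positive_edges(r)
  out <- lapply(grid, function(d) {
    e_target <- round(d * n * (n - 1) / 2)
    truncated <- nrow(ranked) < e_target
    if (truncated) {
      warn(sprintf("positive correlations exhausted at density %.2f", d))
    }
    take <- min(e_target, nrow(ranked))
    adj <- matrix(0L, n, n, dimnames = list(regions, regions))
    if (take > 0) {
      sel <- ranked[seq_len(take), , drop = FALSE]
      adj[sel[, c("i", "j"), drop = FALSE]] <- 1L
      adj[sel[, c("j", "i"), drop = FALSE]] <- 1L
    }
    new_binary_network(adj, regions, d, truncated)
  })
  names(out) <- format(grid)
  out
}

#' @export
print.covnet_network <- function(x, ...) {
  cat(sprintf(
    "<covnet_network> %d regions, %d edges (density %.3f%s)\n",
    length(x$regions), x$k_nonzero / 2, x$density,
    if (x$truncated) ", truncated" else ""
  ))
  invisible(x)
}

#' Convert a binary network to an igraph object
#'
#' @param net A `covnet_network`.
#' @return An undirected `igraph` graph carrying region names.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "covnet_network"))
  igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected")
}

#' Extract the undirected edge list of a binary network
#'
#' @param net A `covnet_network`.
#' @return Tibble with columns `region_a`, `region_b` (each edge once,
#'   `region_a` preceding `region_b` in region order).
#' @export
edge_list <- function(net) {
  stopifnot(inherits(net, "covnet_network"))
  idx <- which(upper.tri(net$adjacency) & net$adjacency == 1L, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])
  tibble(
    region_a = net$regions[idx[ord, 1]],
    region_b = net$regions[idx[ord, 2]]
  )
}

#' Write a binary network to disk
#'
#' `write_adjacency()` writes the 0/1 matrix as TSV with region names as
#' header row and first column; `write_edge_list()` writes the undirected
#' edge list as two tab-separated region-name columns.
#'
#' @param net A `covnet_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(net, path) {
  stopifnot(inherits(net, "covnet_network"))
  df <- as.data.frame(net$adjacency)
  df <- cbind(region = net$regions, df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_adjacency
#' @export
write_edge_list <- function(net, path) {
  readr::write_tsv(edge_list(net), path)
  invisible(path)
}
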