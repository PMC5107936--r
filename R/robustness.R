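# Resilience of a binary network to element removal, summarised as the
# relative size of the largest connected component (LCC / total regions)
# as a function of the fraction of nodes or edges removed.

relative_lcc <- function(g, n_total) {
  if (igraph::vcount(g) == 0) return(0)
  max(igraph::components(g)$csize) / n_total
}

new_robustness_curve <- function(df, mode, type, n_reps) {
  structure(df, class = c("covnet_robustness", class(df)),
            mode = mode, type = type, n_reps = n_reps)
}

#' Random-failure robustness curve
#'
#' Removes a random fraction of nodes or edges and records the mean
#' relative size of the largest connected component across repetitions.
#' Each repetition draws one random removal order and takes prefixes of it
#' across the fraction grid, so every repetition's curve — and hence the
#' mean curve — is non-increasing by construction, while the removed set at
#' each fraction is still a uniform random subset of the stated size
#' (rounded to the nearest count).
#'
#' @param net A `covnet_network` with >= 1 edge.
#' @param mode `"node"` or `"edge"`.
#' @param n_reps Number of random repetitions (default 1000).
#' @param seed Integer seed.
#' @param fractions Removal-fraction grid (default 0 to 1 by 0.05).
#' @return A `covnet_robustness` tibble with columns `fraction`,
#'   `relative_size` (mean over repetitions) and `sd`.
#' @export
random_failure_curve <- function(net, mode = c("node", "edge"),
                                 n_reps = 1000, seed = 1,
                                 fractions = seq(0, 1, by = 0.05)) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "covnet_network"))
  if (net$k_nonzero == 0) abort("robustness curve needs at least one edge")
  if (n_reps < 1) abort("n_reps must be at least 1")
  g <- as_igraph(net)
  n_total <- igraph::vcount(g)
  n_items <- if (mode == "node") n_total else igraph::ecount(g)
  counts <- round(fractions * n_items)

  sizes <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_reps), function(rep) {
      ord <- sample.int(n_items)
      vapply(counts, function(k) {
        if (k == 0) return(relative_lcc(g, n_total))
        g2 <- if (mode == "node") {
          igraph::delete_vertices(g, ord[seq_len(k)])
        } else {
          igraph::delete_edges(g, ord[seq_len(k)])
        }
        relative_lcc(g2, n_total)
      }, numeric(1))
    }, numeric(length(fractions)))
  })
  new_robustness_curve(
    tibble(
      fraction = fractions,
      relative_size = rowMeans(sizes),
      sd = apply(sizes, 1, stats::sd)
    ),
    mode = paste0("random_", mode), type = "random", n_reps = n_reps
  )
}

#' Targeted-attack robustness curve
#'
#' Removes nodes (or edges) cumulatively in decreasing order of their
#' betweenness centrality and records the relative size of the largest
#' connected component after each grid fraction. By default the ordering is
#' computed once on the intact network (static attack); with
#' `recompute = TRUE` the betweenness ranking is recomputed after every
#' single removal (adaptive attack). Ties are broken by region index (node
#' mode) or lexicographic endpoint pair (edge mode).
#'
#' @param net A `covnet_network` with >= 1 edge.
#' @param mode `"node"` or `"edge"`.
#' @param fractions Removal-fraction grid (default 0 to 1 by 0.05).
#' @param recompute Recompute betweenness after each removal? Default
#'   `FALSE`.
#' @return A `covnet_robustness` tibble with columns `fraction` and
#'   `relative_size`.
#' @export
targeted_attack_curve <- function(net, mode = c("node", "edge"),
                                  fractions = seq(0, 1, by = 0.05),
                                  recompute = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "covnet_network"))
  if (net$k_nonzero == 0) abort("robustness curve needs at least one edge")
  g <- as_igraph(net)
  n_total <- igraph::vcount(g)
  n_items <- if (mode == "node") n_total else igraph::ecount(g)
  counts <- round(fractions * n_items)

  item_order <- function(gr) {
    # decreasing betweenness; deterministic tie-breaks
    if (mode == "node") {
      b <- igraph::betweenness(gr, directed = FALSE)
      order(-b, seq_along(b))
    } else {
      b <- igraph::edge_betweenness(gr, directed = FALSE)
      el <- igraph::as_edgelist(gr, names = FALSE)
      order(-b, pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    }
  }

  sizes <- numeric(length(fractions))
  if (!recompute) {
    ord <- item_order(g)
    for (fi in seq_along(counts)) {
      k <- counts[fi]
      g2 <- if (k == 0) g else if (mode == "node") {
        igraph::delete_vertices(g, ord[seq_len(k)])
      } else {
        igraph::delete_edges(g, ord[seq_len(k)])
      }
      sizes[fi] <- relative_lcc(g2, n_total)
    }
  } else {
    # adaptive: remove one element at a time, re-ranking each step
    g2 <- g
    removed <- 0L
    for (fi in seq_along(counts)) {
      while (removed < counts[fi] &&
             (if (mode == "node") igraph::vcount(g2) else igraph::ecount(g2)) > 0) {
        top <- item_order(g2)[1]
        g2 <- if (mode == "node") igraph::delete_vertices(g2, top) else
          igraph::delete_edges(g2, top)
        removed <- removed + 1L
      }
      sizes[fi] <- relative_lcc(g2, n_total)
    }
  }
  new_robustness_curve(
    tibble(fraction = fractions, relative_size = sizes),
    mode = paste0("targeted_", mode), type = "targeted", n_reps = 1L
  )
}

#' @export
print.covnet_robustness <- function(x, ...) {
  cat(sprintf("<covnet_robustness> %s, %d fractions, n_reps = %d\n",
              attr(x, "mode"), nrow(x), attr(x, "n_reps")))
  NextMethod()
}

#' Write a robustness curve as TSV
#'
#' Columns: fraction, mean relative size, and (for random curves) the
#' standard deviation across repetitions.
#'
#' @param curve A `covnet_robustness` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_robustness_curve <- function(curve, path) {
  readr::write_tsv(as_tibble(curve), path)
  invisible(path)
}
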