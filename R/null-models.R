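#' Degree-preserving randomisation of a binary network
#'
#' Maslov-Sneppen double-edge-swap rewiring: repeatedly picks two edges and
#' exchanges their endpoints, rejecting swaps that would create self-loops
#' or multi-edges, so every node keeps its exact degree. With
#' `n_swaps_per_edge = 0` the network is returned unchanged (the identity
#' null).
#'
#' @param net A `covnet_network` with >= 2 edges (returned unchanged, with
#'   a warning, below that).
#' @param n_swaps_per_edge Attempted swaps per edge (default 10).
#' @param seed Integer seed; same seed gives the same rewiring.
#' @return A `covnet_network` with identical degree sequence and density.
#' @export
rewire_degree_preserving <- function(net, n_swaps_per_edge = 10, seed = 1) {
  stopifnot(inherits(net, "covnet_network"))
  g <- as_igraph(net)
  n_edges <- igraph::ecount(g)
  if (n_edges < 2) {
    warn("fewer than 2 edges; returning network unchanged")
    return(net)
  }
  niter <- as.integer(round(n_swaps_per_edge * n_edges))
  if (niter == 0) return(net)
  g2 <- withr::with_seed(as.integer(seed),
                         igraph::rewire(g, igraph::keeping_degseq(niter = niter)))
  adj <- igraph::as_adjacency_matrix(g2, sparse = FALSE)
  storage.mode(adj) <- "integer"
  dimnames(adj) <- list(net$regions, net$regions)
  new_binary_network(adj, net$regions, net$target_density, net$truncated)
}

#' Small-world coefficients against a rewired null ensemble
#'
#' Computes gamma = Cp / mean(Cp_null), lambda = Lp / mean(Lp_null) and
#' sigma = gamma / lambda, where the null ensemble consists of `n_nulls`
#' degree-preserving rewirings of the empirical network ([rewire_degree_preserving()]).
#' Null networks inherit the node set, and their path lengths use the same
#' reachable-pair convention as the empirical network. sigma > 1 indicates
#' small-world organisation: clustering well above, path length near, the
#' random expectation.
#'
#' @param net A `covnet_network` with >= 1 edge.
#' @param n_nulls Ensemble size (default 100).
#' @param seed Integer seed; each null gets an independent derived seed.
#' @param n_swaps_per_edge Swaps per edge for each null (default 10; 0
#'   gives the identity ensemble with gamma = lambda = sigma = 1).
#' @return An object of class `covnet_smallworld`: list with `gamma`,
#'   `lambda`, `sigma`, `cp`, `lp`, `cp_rand`, `lp_rand`, `cp_values`,
#'   `lp_values`, `n_nulls`.
#' @export
#' @examples
#' specs <- default_cohort_specs(n_regions = 20)
#' cohort <- generate_cohort(specs$control, specs$patient, 30, 30, seed = 1)
#' net <- cohort |> correlation_matrix("A") |> threshold_at_density(0.19)
#' small_world_params(net, n_nulls = 10, seed = 1)
small_world_params <- function(net, n_nulls = 100, seed = 1,
                               n_swaps_per_edge = 10) {
  if (n_nulls < 1) abort("n_nulls must be at least 1")
  cp <- clustering_coefficient(net)
  lp <- characteristic_path_length(net)
  seeds <- derive_seeds(seed, n_nulls)
  g <- as_graph(net)
  niter <- as.integer(round(n_swaps_per_edge * igraph::ecount(g)))
  if (niter == 0 || igraph::ecount(g) < 2) {
    # identity ensemble: every null is the network itself
    cp_values <- rep(cp, n_nulls)
    lp_values <- rep(lp, n_nulls)
  } else {
    nulls <- lapply(seq_len(n_nulls), function(i) {
      g2 <- withr::with_seed(
        seeds[i], igraph::rewire(g, igraph::keeping_degseq(niter = niter))
      )
      adj2 <- igraph::as_adjacency_matrix(g2, sparse = FALSE)
      c(cp = fast_cp(adj2), lp = {
        d <- fast_distances(adj2)[upper.tri(adj2)]
        mean(d[is.finite(d)])
      })
    })
    cp_values <- vapply(nulls, `[[`, numeric(1), "cp")
    lp_values <- vapply(nulls, `[[`, numeric(1), "lp")
  }
  cp_rand <- mean(cp_values)
  lp_rand <- mean(lp_values)
  if (cp_rand == 0 || lp_rand == 0) {
    abort("null ensemble mean Cp or Lp is zero; small-world coefficients undefined")
  }
  gamma <- cp / cp_rand
  lambda <- lp / lp_rand
  structure(
    list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
         cp = cp, lp = lp, cp_rand = cp_rand, lp_rand = lp_rand,
         cp_values = cp_values, lp_values = lp_values, n_nulls = n_nulls),
    class = "covnet_smallworld"
  )
}

#' @export
print.covnet_smallworld <- function(x, ...) {
  cat(sprintf(
    "<covnet_smallworld> gamma = %.3f, lambda = %.3f, sigma = %.3f (%d nulls)\n",
    x$gamma, x$lambda, x$sigma, x$n_nulls
  ))
  invisible(x)
}

#' @method tidy covnet_smallworld
#' @export
tidy.covnet_smallworld <- function(x, ...) {
  tibble(
    gamma = x$gamma, lambda = x$lambda, sigma = x$sigma,
    cp = x$cp, lp = x$lp, cp_rand = x$cp_rand, lp_rand = x$lp_rand,
    n_nulls = x$n_nulls
  )
}
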