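# Node- and network-level statistics on binary networks. Conventions for
# disconnected graphs: characteristic path length averages over mutually
# reachable pairs only (keeps Lp finite at the sparse end of the density
# grid); efficiency treats unreachable pairs as 1/infinity = 0; nodes with
# degree < 2 contribute 0 (not NA) to the clustering and local-efficiency
# means so denominators stay fixed across groups.

as_graph <- function(net) {
  if (inherits(net, "igraph")) return(net)
  as_igraph(net)
}

get_adj <- function(net) {
  if (inherits(net, "covnet_network")) return(net$adjacency)
  if (inherits(net, "igraph")) {
    return(igraph::as_adjacency_matrix(net, sparse = FALSE))
  }
  if (is.matrix(net)) return(net)
  abort("expected a covnet_network, igraph graph or adjacency matrix")
}

# All-pairs shortest-path hop counts by breadth-first search expressed as
# boolean matrix products (one product per BFS level); Inf where
# unreachable. For the dense small matrices of this pipeline this is much
# faster than per-call graph construction.
fast_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  if (n == 0 || sum(adj) == 0) return(d)
  reach <- adj > 0
  d[reach] <- 1
  diag(reach) <- TRUE
  level <- 1
  repeat {
    nxt <- (reach %*% adj) > 0
    new <- nxt & !reach
    if (!any(new)) break
    level <- level + 1
    d[new] <- level
    reach <- reach | nxt
  }
  d
}

fast_cp <- function(adj) {
  k <- rowSums(adj)
  if (all(k < 2)) return(0)
  closed3 <- diag(adj %*% adj %*% adj) # 2 * triangles through each node
  mean(ifelse(k < 2, 0, closed3 / (k * (k - 1))))
}

fast_geff <- function(adj) {
  n <- nrow(adj)
  if (n < 2 || sum(adj) == 0) return(0)
  inv <- 1 / fast_distances(adj)
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Mean clustering coefficient
#'
#' Mean over nodes of the local clustering coefficient
#' `2 * triangles_i / (k_i * (k_i - 1))`; nodes with degree < 2 contribute
#' 0. A segregation measure: the fraction of each node's neighbour pairs
#' that are themselves connected.
#'
#' @param net A `covnet_network` (or igraph graph).
#' @return Scalar in `[0, 1]`.
#' @export
clustering_coefficient <- function(net) {
  fast_cp(get_adj(net))
}

#' Characteristic path length
#'
#' Mean shortest-path hop count over all pairs of distinct nodes that are
#' mutually reachable; pairs in different components are excluded from the
#' average. An integration measure.
#'
#' @param net A `covnet_network` (or igraph graph) with at least one edge.
#' @return Scalar >= 1.
#' @export
characteristic_path_length <- function(net) {
  adj <- get_adj(net)
  if (sum(adj) == 0) abort("path length undefined: network has no edges")
  d <- fast_distances(adj)[upper.tri(adj)]
  mean(d[is.finite(d)])
}

#' Global efficiency
#'
#' Mean over ordered pairs of distinct nodes of the inverse shortest-path
#' length, with unreachable pairs contributing 0. Equals 1 exactly on a
#' complete graph; robust to disconnection.
#'
#' @param net A `covnet_network` (or igraph graph).
#' @return Scalar in `[0, 1]`.
#' @export
global_efficiency <- function(net) {
  fast_geff(get_adj(net))
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of the subgraph induced on each
#' node's neighbours; nodes with fewer than 2 neighbours contribute 0.
#' Reflects short-range (neighbourhood-level) fault tolerance.
#'
#' @param net A `covnet_network` (or igraph graph).
#' @return Scalar in `[0, 1]`.
#' @export
local_efficiency <- function(net) {
  adj <- get_adj(net)
  n <- nrow(adj)
  if (n == 0 || sum(adj) == 0) return(0)
  vals <- vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] > 0)
    if (length(nb) < 2) return(0)
    fast_geff(adj[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(vals)
}

#' Modularity and module partition
#'
#' Finds a module partition by seeded Louvain modularity maximisation (best
#' of `n_restarts` restarts kept) and scores it with the Newman-Girvan
#' quality `Q = sum_c (e_c / m - (d_c / 2m)^2)`: the within-module edge
#' fraction in excess of its degree-matched random expectation.
#'
#' @param net A `covnet_network` (or igraph graph) with >= 1 edge.
#' @param seed Integer seed for the heuristic.
#' @param n_restarts Number of restarts (default 20).
#' @return List with elements `q` (scalar <= 1) and `partition` (named
#'   integer vector of module labels per region).
#' @export
network_modularity <- function(net, seed = 1, n_restarts = 20) {
  g <- as_graph(net)
  if (igraph::ecount(g) == 0) abort("modularity undefined: network has no edges")
  best <- withr::with_seed(as.integer(seed), {
    runs <- lapply(seq_len(n_restarts), function(i) {
      cl <- igraph::cluster_louvain(g)
      m <- igraph::membership(cl)
      list(q = igraph::modularity(g, m), partition = m)
    })
    runs[[which.max(vapply(runs, `[[`, numeric(1), "q"))]]
  })
  part <- as.integer(best$partition)
  names(part) <- igraph::V(g)$name
  list(q = best$q, partition = part)
}

#' Node betweenness centrality
#'
#' Shortest-path betweenness with fractional credit across all shortest
#' paths and endpoints excluded (unnormalised counts).
#'
#' @param net A `covnet_network` (or igraph graph).
#' @return Tibble with columns `region` and `betweenness`.
#' @export
node_betweenness <- function(net) {
  g <- as_graph(net)
  b <- igraph::betweenness(g, directed = FALSE)
  tibble(region = igraph::V(g)$name %||% as.character(seq_along(b)),
         betweenness = unname(b))
}

#' Identify betweenness hubs
#'
#' Hubs are nodes whose betweenness exceeds twice the network-mean
#' betweenness. The table reports the raw betweenness, the normalised
#' betweenness (raw divided by the network mean, so its average over
#' regions is 1), and the hub flag, sorted by normalised betweenness
#' descending.
#'
#' @param net A `covnet_network` (or igraph graph) with >= 1 edge.
#' @return A tibble of class `covnet_hubs` with columns `region`,
#'   `betweenness`, `normalized_betweenness`, `is_hub`.
#' @export
#' @examples
#' g <- igraph::make_star(5, mode = "undirected")
#' identify_hubs(g) # centre has normalised betweenness 5, sole hub
identify_hubs <- function(net) {
  g <- as_graph(net)
  if (igraph::ecount(g) == 0) abort("hub detection needs at least one edge")
  tab <- node_betweenness(g)
  mb <- mean(tab$betweenness)
  if (mb == 0) {
    warn("all betweenness values are zero; no hubs identifiable")
    tab$normalized_betweenness <- NA_real_
    tab$is_hub <- FALSE
  } else {
    tab$normalized_betweenness <- tab$betweenness / mb
    tab$is_hub <- tab$normalized_betweenness > 2
    tab <- dplyr::arrange(tab, dplyr::desc(.data$normalized_betweenness))
  }
  class(tab) <- c("covnet_hubs", class(tab))
  tab
}

#' Relative size of the largest connected component
#'
#' Order of the largest mutually reachable subnetwork divided by the total
#' number of regions; isolated nodes count as components of size 1.
#'
#' @param net A `covnet_network` (or igraph graph).
#' @return Fraction in `(0, 1]`.
#' @export
largest_component_relative_size <- function(net) {
  g <- as_graph(net)
  max(igraph::components(g)$csize) / igraph::vcount(g)
}

#' All network-level metrics of a binary network
#'
#' Convenience wrapper returning the five network-level statistics in one
#' row; for the small-world coefficients (which need a null ensemble) see
#' [small_world_params()].
#'
#' @param net A `covnet_network` (or igraph graph).
#' @param seed Seed for the modularity heuristic.
#' @param n_restarts Modularity restarts.
#' @return One-row tibble with columns `cp`, `lp`, `e_glob`, `e_loc`, `q`.
#' @export
network_metrics <- function(net, seed = 1, n_restarts = 20) {
  tibble(
    cp = clustering_coefficient(net),
    lp = characteristic_path_length(net),
    e_glob = global_efficiency(net),
    e_loc = local_efficiency(net),
    q = network_modularity(net, seed = seed, n_restarts = n_restarts)$q
  )
}

#' Write a hub table as TSV
#'
#' @param hubs A `covnet_hubs` tibble from [identify_hubs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hub_table <- function(hubs, path) {
  readr::write_tsv(hubs, path)
  invisible(path)
}
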