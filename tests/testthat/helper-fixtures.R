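# Small programmatic fixtures shared across test files.

# Build a covnet_network from an explicit undirected edge list.
net_from_edges <- function(n, edges, regions = sprintf("r%02d", seq_len(n))) {
  adj <- matrix(0L, n, n, dimnames = list(regions, regions))
  if (length(edges)) {
    e <- matrix(edges, ncol = 2, byrow = TRUE)
    adj[e] <- 1L
    adj[e[, 2:1, drop = FALSE]] <- 1L
  }
  covnet:::new_binary_network(adj, regions,
                              sum(adj) / (n * (n - 1)))
}

net_from_adj <- function(adj) {
  n <- nrow(adj)
  regions <- sprintf("r%02d", seq_len(n))
  dimnames(adj) <- list(regions, regions)
  storage.mode(adj) <- "integer"
  covnet:::new_binary_network(adj, regions, sum(adj) / (n * (n - 1)))
}

# Random connected simple graph on n nodes (rejection sampling).
random_connected_adj <- function(n, p = 0.5) {
  repeat {
    adj <- matrix(0L, n, n)
    up <- which(upper.tri(adj))
    on <- up[stats::runif(length(up)) < p]
    adj[on] <- 1L
    adj <- adj + t(adj)
    if (sum(adj) > 0 && all(is.finite(oracle_distances(adj)))) return(adj)
  }
}

complete_net <- function(n) {
  adj <- matrix(1L, n, n)
  diag(adj) <- 0L
  net_from_adj(adj)
}

star_net <- function(n) net_from_edges(n, as.vector(rbind(1, 2:n)))

ring_net <- function(n) {
  net_from_edges(n, as.vector(rbind(seq_len(n), c(2:n, 1))))
}

path_net <- function(n) net_from_edges(n, as.vector(rbind(1:(n - 1), 2:n)))

# Ring lattice: each node connected to its k nearest neighbours (k even).
ring_lattice_net <- function(n, k) {
  edges <- integer()
  for (j in seq_len(k / 2)) {
    to <- ((seq_len(n) - 1 + j) %% n) + 1
    edges <- c(edges, as.vector(rbind(seq_len(n), to)))
  }
  net_from_edges(n, edges)
}

# Small two-group cohort for pipeline-level tests.
small_cohort <- function(n_regions = 10, n_a = 15, n_b = 15, seed = 42,
                         r_within_b = 0.35) {
  specs <- default_cohort_specs(n_regions = n_regions, n_modules = 2,
                                r_within_patient = r_within_b)
  generate_cohort(specs$control, specs$patient, n_a, n_b, seed = seed)
}
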