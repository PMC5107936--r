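# Independent brute-force implementations of every graph statistic, written
# directly from the definitions in plain R (no igraph), used as oracles
# against the package's implementations on small graphs.

# Breadth-first-search distance matrix; Inf where unreachable.
oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    depth <- 0
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- integer()
      for (v in frontier) {
        for (w in which(adj[v, ] == 1)) {
          if (is.infinite(d[s, w]) && w != s) {
            d[s, w] <- depth
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  d
}

# Mean local clustering; degree-<2 nodes contribute 0.
oracle_cp <- function(adj) {
  n <- nrow(adj)
  mean(vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(adj[nb, nb]) / 2
    2 * links / (k * (k - 1))
  }, numeric(1)))
}

# Mean shortest path over mutually reachable unordered pairs.
oracle_lp <- function(adj) {
  d <- oracle_distances(adj)
  vals <- d[upper.tri(d)]
  mean(vals[is.finite(vals)])
}

oracle_geff <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(0)
  d <- oracle_distances(adj)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0 # unreachable
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_leff <- function(adj) {
  n <- nrow(adj)
  mean(vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] == 1)
    if (length(nb) < 2) return(0)
    oracle_geff(adj[nb, nb, drop = FALSE])
  }, numeric(1)))
}

# Betweenness by exhaustive enumeration of all simple paths between every
# pair; shortest ones share credit fractionally, endpoints excluded.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  paths_between <- function(s, t) {
    out <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) {
        out[[length(out) + 1]] <<- path
        return()
      }
      for (w in which(adj[v, ] == 1)) {
        if (!w %in% path) walk(c(path, w))
      }
    }
    walk(s)
    out
  }
  b <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq((s + 1), n)) {
      ps <- paths_between(s, t)
      if (!length(ps)) next
      lens <- vapply(ps, length, integer(1))
      shortest <- ps[lens == min(lens)]
      for (p in shortest) {
        interior <- setdiff(p, c(s, t))
        b[interior] <- b[interior] + 1 / length(shortest)
      }
    }
  }
  b
}

# Newman-Girvan modularity of a given partition, from the definition.
oracle_modularity <- function(adj, membership) {
  m <- sum(adj) / 2
  deg <- rowSums(adj)
  q <- 0
  for (c in unique(membership)) {
    idx <- which(membership == c)
    e_c <- sum(adj[idx, idx]) / 2
    d_c <- sum(deg[idx])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}
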