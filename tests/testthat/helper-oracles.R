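# Independent brute-force oracles, deliberately naive: Floyd-Warshall
# distances, geodesic counting by adjacency powers, direct triangle counts.
# They share no code with the package's igraph-backed implementations.

# adjacency matrix of the simplified graph of an interaction_network
net_adjacency <- function(net) {
  nodes <- net$nodes$node
  n <- length(nodes)
  adj <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(net$edges))) {
    a <- net$edges$node_a[[i]]
    b <- net$edges$node_b[[i]]
    adj[a, b] <- 1L
    adj[b, a] <- 1L
  }
  adj
}

# all-pairs shortest path lengths by Floyd-Warshall
oracle_dist <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# number of geodesics between every pair: walks of length dist(s,t) counted
# via powers of the adjacency matrix (a walk of geodesic length is a path)
oracle_geodesic_counts <- function(adj, d) {
  n <- nrow(adj)
  maxd <- max(d[is.finite(d)])
  powers <- vector("list", max(maxd, 1))
  powers[[1]] <- adj
  if (maxd >= 2) {
    for (k in 2:maxd) powers[[k]] <- powers[[k - 1]] %*% adj
  }
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s != t && is.finite(d[s, t])) sigma[s, t] <- powers[[d[s, t]]][s, t]
    }
  }
  sigma
}

# unnormalized vertex betweenness with fractional credit for tied geodesics
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_dist(adj)
  sigma <- oracle_geodesic_counts(adj, d)
  btw <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == v || t == v || !is.finite(d[s, t])) next
        if (d[s, v] + d[v, t] == d[s, t]) {
          btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  stats::setNames(btw, rownames(adj))
}

# mean local clustering coefficient, nodes with < 2 neighbours scoring 0
oracle_clustering <- function(adj) {
  n <- nrow(adj)
  if (n == 0) {
    return(NA_real_)
  }
  local <- vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] == 1)
    k <- length(nb)
    if (k < 2) {
      return(0)
    }
    links <- sum(adj[nb, nb]) / 2
    2 * links / (k * (k - 1))
  }, numeric(1))
  mean(local)
}

oracle_components <- function(adj) {
  d <- oracle_dist(adj)
  seen <- rep(FALSE, nrow(adj))
  comps <- 0L
  for (v in seq_len(nrow(adj))) {
    if (!seen[v]) {
      comps <- comps + 1L
      seen[is.finite(d[v, ])] <- TRUE
    }
  }
  comps
}

oracle_path_stats <- function(adj) {
  d <- oracle_dist(adj)
  vals <- d[upper.tri(d)]
  vals <- vals[is.finite(vals) & vals > 0]
  if (length(vals) == 0) {
    return(list(diameter = NA_real_, cpl = NA_real_))
  }
  list(diameter = max(vals), cpl = mean(vals))
}

# Erdos-Renyi-ish random multigraph as an interaction_network; occasionally
# adds a parallel curated edge to exercise multiplicity handling
random_network <- function(n_nodes, p = 0.4, p_multi = 0.2) {
  nodes <- as.character(seq_len(n_nodes))
  edges <- NULL
  if (n_nodes >= 2) {
    cmb <- combn(nodes, 2)
    pick <- stats::runif(ncol(cmb)) < p
    if (any(pick)) {
      edges <- tibble::tibble(
        node_a = cmb[1, pick], node_b = cmb[2, pick],
        relation = sample(c("reg", "pos_reg", "neg_reg", "binding"), sum(pick), replace = TRUE),
        origin = "TEXT_MINED"
      )
      dup <- stats::runif(nrow(edges)) < p_multi
      if (any(dup)) {
        extra <- edges[dup, ]
        extra$relation <- "pos_reg"
        edges <- dplyr::bind_rows(edges, extra)
      }
    }
  }
  interaction_network(edges, tibble::tibble(node = nodes, kind = "GENE"))
}

# brute-force interval union over connected overlap components: intervals
# [start, end) belong together iff they share >= 1 position, transitively
# (adjacent intervals touching at a boundary stay separate)
oracle_interval_union <- function(starts, ends) {
  n <- length(starts)
  if (n == 0) {
    return(matrix(numeric(0), ncol = 2))
  }
  ov <- outer(seq_len(n), seq_len(n), function(i, j) {
    starts[i] < ends[j] & starts[j] < ends[i]
  })
  # transitive closure by repeated squaring of the boolean relation
  repeat {
    nxt <- (ov %*% ov) > 0 | ov
    if (identical(nxt, ov)) break
    ov <- nxt
  }
  comp <- rep(NA_integer_, n)
  k <- 0
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      k <- k + 1
      comp[which(ov[i, ])] <- k
    }
  }
  out <- t(vapply(seq_len(k), function(cc) {
    c(min(starts[comp == cc]), max(ends[comp == cc]))
  }, numeric(2)))
  out[order(out[, 1]), , drop = FALSE]
}
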