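# Brute-force reference implementations for network properties, written
# directly against the adjacency matrix so they share no code path with the
# package's igraph-backed analytics. Intended for tiny graphs only.

# adj: square 0/1 matrix, no self-loops, dimnames optional.
bf_graph <- function(adj) {
  n <- nrow(adj)
  if (is.null(rownames(adj))) {
    nm <- sprintf("v%04d", seq_len(n))
    dimnames(adj) <- list(nm, nm)
  }
  adj
}

bf_und <- function(adj) (adj + t(adj)) > 0

# boolean transitive closure by repeated squaring
bf_closure <- function(B) {
  n <- nrow(B)
  R <- B | diag(TRUE, n)
  repeat {
    R2 <- (R %*% R) > 0
    if (all(R2 == R)) return(R)
    R <- R2
  }
}

bf_components <- function(adj) {   # weak components
  R <- bf_closure(bf_und(adj))
  memb <- integer(nrow(adj))
  k <- 0L
  for (i in seq_len(nrow(adj))) {
    if (memb[i] == 0L) { k <- k + 1L; memb[R[i, ]] <- k }
  }
  memb
}

bf_dist <- function(und_sub) {     # Floyd-Warshall on an undirected 0/1 matrix
  n <- nrow(und_sub)
  D <- ifelse(und_sub, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

bf_clustering <- function(adj) {   # average local clustering, isolates = 0
  und <- bf_und(adj)
  n <- nrow(und)
  mean(vapply(seq_len(n), function(i) {
    nb <- which(und[i, ])
    if (length(nb) < 2) return(0)
    links <- sum(und[nb, nb]) / 2
    links / choose(length(nb), 2)
  }, 0))
}

bf_cyclic_nodes <- function(adj) { # nodes in strongly connected comps >= 2
  R <- bf_closure(adj > 0)
  mutual <- R & t(R)
  diag(mutual) <- FALSE
  sum(apply(mutual, 1, any))
}

# connectivity of a connected undirected graph by exhaustive removal
bf_edge_connectivity <- function(und_sub) {
  n <- nrow(und_sub)
  if (n < 2) return(0)
  el <- which(und_sub & upper.tri(und_sub), arr.ind = TRUE)
  m <- nrow(el)
  connected <- function(u) {
    memb <- bf_components(ifelse(u, 1, 0))
    all(memb == memb[1])
  }
  for (k in 0:m) {
    for (drop in if (k == 0) list(integer(0)) else
         asplit(combn(m, k), 2)) {
      u <- und_sub
      for (e in drop) { u[el[e, 1], el[e, 2]] <- FALSE; u[el[e, 2], el[e, 1]] <- FALSE }
      if (!connected(u)) return(k)
    }
  }
  m
}

bf_vertex_connectivity <- function(und_sub) {
  n <- nrow(und_sub)
  if (n < 2) return(0)
  connected <- function(u) {
    if (nrow(u) <= 1) return(TRUE)
    memb <- bf_components(ifelse(u, 1, 0))
    all(memb == memb[1])
  }
  for (k in 0:(n - 2)) {
    for (drop in if (k == 0) list(integer(0)) else
         asplit(combn(n, k), 2)) {
      u <- und_sub[setdiff(seq_len(n), drop), setdiff(seq_len(n), drop), drop = FALSE]
      if (!connected(u)) return(k)
    }
  }
  n - 1
}

# full comparable property vector
bf_metrics <- function(adj) {
  adj <- bf_graph(adj)
  n <- nrow(adj); m <- sum(adj)
  und <- bf_und(adj)
  memb <- bf_components(adj)
  sizes <- tabulate(memb)
  big <- which(memb == which.max(sizes))
  D <- bf_dist(und[big, big, drop = FALSE])
  ecc <- apply(D, 1, max)
  list(order = n, size = m,
       density = if (n > 1) m / (n * (n - 1)) else 0,
       mean_degree = m / n,
       mean_total_degree = 2 * m / n,
       clustering = bf_clustering(adj),
       diameter = if (length(big) > 1) max(ecc) else 0,
       radius = if (length(big) > 1) min(ecc) else 0,
       n_components = max(memb),
       largest_component_size = max(sizes),
       n_cyclic_nodes = bf_cyclic_nodes(adj),
       vertex_connectivity = bf_vertex_connectivity(und[big, big, drop = FALSE]),
       edge_connectivity = bf_edge_connectivity(und[big, big, drop = FALSE]),
       max_total_degree = max(rowSums(adj) + colSums(adj)),
       max_in_degree = max(colSums(adj)),
       max_out_degree = max(rowSums(adj)))
}

adj_to_igraph <- function(adj) {
  adj <- bf_graph(adj)
  igraph::graph_from_adjacency_matrix(adj, mode = "directed")
}

# all directed graphs on n nodes (n <= 3: 64 graphs)
enumerate_digraphs <- function(n) {
  slots <- which(row(diag(n)) != col(diag(n)))
  k <- length(slots)
  lapply(0:(2^k - 1), function(code) {
    adj <- matrix(0L, n, n)
    adj[slots] <- as.integer(intToBits(code)[1:k])
    adj
  })
}

random_adj <- function(n, p) {
  adj <- matrix(as.integer(runif(n * n) < p), n, n)
  diag(adj) <- 0L
  adj
}

# brute-force triad census over all node triples; classes identified by a
# canonical code (minimum 6-bit encoding over the 6 vertex permutations)
bf_triad_counts <- function(adj) {
  n <- nrow(adj)
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  canon <- function(sub) {
    min(vapply(perms, function(p) {
      s <- sub[p, p]
      sum(c(s[1, 2], s[1, 3], s[2, 1], s[2, 3], s[3, 1], s[3, 2]) * 2^(0:5))
    }, 0))
  }
  counts <- new.env()
  for (trip in asplit(combn(n, 3), 2)) {
    key <- as.character(canon(adj[trip, trip]))
    counts[[key]] <- (if (is.null(counts[[key]])) 0 else counts[[key]]) + 1
  }
  as.list(counts)
}
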