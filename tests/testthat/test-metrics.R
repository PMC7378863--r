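test_that("density and mean degree follow the directed conventions", {
  # 61 nodes, 62 edges: density 0.017 and mean degree 1.017 at 3 decimals
  g <- igraph::sample_gnm(61, 62, directed = TRUE)
  r <- network_metrics(g, cut_sets = FALSE, powerlaw = FALSE)
  expect_equal(r$density, 62 / (61 * 60))
  expect_equal(round(r$density, 3), 0.017)
  expect_lt(abs(r$mean_degree - 1.017), 0.001)
  expect_equal(r$mean_total_degree, 2 * 62 / 61)
})

test_that("complete directed graph has the closed-form metrics", {
  g <- igraph::make_full_graph(4, directed = TRUE)
  r <- network_metrics(g, cut_sets = FALSE, powerlaw = FALSE)
  expect_equal(r$density, 1)
  expect_equal(r$clustering, 1)
  expect_equal(r$diameter, 1)
  expect_equal(r$radius, 1)
  expect_equal(r$n_components, 1)
  expect_equal(r$n_cyclic_nodes, 4)
  expect_equal(r$vertex_connectivity, 3)
})

test_that("all metrics agree with the brute-force oracle on small graphs", {
  check_graph <- function(adj) {
    ref <- bf_metrics(adj)
    got <- network_metrics(adj_to_igraph(adj), cut_sets = FALSE,
                           powerlaw = FALSE)
    for (prop in names(ref))
      expect_equal(got[[prop]], ref[[prop]], tolerance = 1e-12,
                   label = sprintf("%s (adj %s)", prop,
                                   paste(adj, collapse = "")))
  }
  for (adj in enumerate_digraphs(3)) check_graph(adj)   # exhaustive at n = 3
  set.seed(71)
  for (i in 1:100) check_graph(random_adj(4, runif(1, 0.1, 0.9)))
  for (i in 1:100) check_graph(random_adj(5, runif(1, 0.1, 0.9)))
})

test_that("hub identification matches star closed forms and handles ties", {
  net <- edgelist_network(rep("c", 5), paste0("l", 1:5))
  h <- identify_hubs(net)
  expect_identical(h$hubs_out, "c")
  expect_identical(h$max_out, 5)
  expect_identical(h$max_in, 1)
  expect_identical(h$hubs_in, paste0("l", 1:5))
  expect_identical(h$hubs_total, "c")

  tie <- edgelist_network(c("a", "b", "a", "b"), c("x", "x", "y", "y"))
  ht <- identify_hubs(tie)
  expect_identical(ht$hubs_total, c("a", "b", "x", "y"))
  expect_identical(ht$max_total, 2)
})

test_that("hub argmax sets match brute-force tallies on random graphs", {
  set.seed(72)
  for (i in 1:20) {
    adj <- random_adj(20, 0.1)
    h <- identify_hubs(adj_to_igraph(adj))
    tot <- rowSums(adj) + colSums(adj)
    nm <- rownames(bf_graph(adj))
    expect_identical(h$hubs_total, sort(nm[tot == max(tot)]))
    expect_equal(h$max_total, max(tot))
    expect_equal(h$max_in, max(colSums(adj)))
    expect_equal(h$max_out, max(rowSums(adj)))
  }
})

test_that("hub identification is label-permutation equivariant", {
  set.seed(73)
  adj <- random_adj(12, 0.2)
  nm <- sprintf("g%02d", 1:12)
  dimnames(adj) <- list(nm, nm)
  h1 <- identify_hubs(adj_to_igraph(adj))
  perm <- sample(12)
  adj2 <- adj[perm, perm]
  h2 <- identify_hubs(adj_to_igraph(adj2))
  expect_identical(h1$hubs_total, h2$hubs_total)
  expect_identical(h1$max_in, h2$max_in)
})

test_that("greedy community detection finds the obvious partitions", {
  tri2 <- igraph::graph_from_literal(a - b, b - c, c - a, d - e, e - f, f - d)
  cm <- detect_communities(tri2)
  expect_identical(cm$n_modules, 2L)
  expect_equal(cm$modularity, 0.5)
  expect_identical(unname(cm$membership[c("a", "b", "c")]), rep(1L, 3))

  lonely <- igraph::make_empty_graph(4, directed = TRUE)
  igraph::V(lonely)$name <- letters[1:4]
  cm0 <- detect_communities(lonely)
  expect_identical(cm0$n_modules, 4L)
  expect_equal(cm0$modularity, 0)
})

test_that("reported modularity equals the direct Newman formula", {
  set.seed(74)
  for (i in 1:15) {
    g <- igraph::sample_gnm(15, sample(10:30, 1), directed = TRUE)
    igraph::V(g)$name <- sprintf("v%04d", 1:15)
    cm <- detect_communities(g)
    expect_equal(cm$modularity, newman_modularity(g, cm$membership),
                 tolerance = 1e-12)
    expect_equal(sum(cm$module_sizes), 15L)
    # cross-check against igraph's own modularity evaluation
    und <- igraph::as_undirected(g, mode = "collapse")
    expect_equal(cm$modularity,
                 igraph::modularity(und, cm$membership[igraph::V(und)$name]),
                 tolerance = 1e-12)
  }
})

test_that("the greedy maximal independent set is independent and maximal", {
  set.seed(75)
  for (i in 1:20) {
    g <- igraph::sample_gnm(12, 20, directed = TRUE)
    igraph::V(g)$name <- sprintf("v%04d", 1:12)
    r <- network_metrics(g, cut_sets = FALSE, powerlaw = FALSE)
    mis <- r$independent_set
    und <- igraph::as_undirected(g, mode = "collapse")
    A <- igraph::as_adjacency_matrix(und, sparse = FALSE)
    nm <- igraph::V(und)$name
    idx <- match(mis, nm)
    expect_true(all(A[idx, idx] == 0))                  # independence
    outside <- setdiff(seq_along(nm), idx)
    expect_true(all(rowSums(A[outside, idx, drop = FALSE]) > 0))  # maximality
  }
})

test_that("minimum cut sets disconnect the largest component", {
  net <- edgelist_network(c("a", "b", "c", "c"), c("b", "c", "a", "d"))
  r <- network_metrics(net)
  expect_identical(r$vertex_connectivity, 1)
  expect_identical(r$vertex_cut, "c")     # articulation point to d
  expect_identical(r$edge_connectivity, 1)
  expect_identical(r$edge_cut, "c--d")
})

test_that("power-law exponent recovers from parametric draws", {
  set.seed(76)
  k <- 1:100000
  x <- sample(k, 10000, replace = TRUE, prob = k^(-2.5))
  fit <- powerlaw_fit(x)
  expect_equal(fit$alpha, 2.5, tolerance = 0.1)
  expect_lt(fit$ks, 0.05)

  sub <- sample(x, 5000)
  fit2 <- powerlaw_fit(sub)
  expect_equal(fit2$alpha, fit$alpha, tolerance = 0.3)

  expect_warning(fd <- powerlaw_fit(rep(3, 10)), "poorly identified")
  expect_true(fd$degenerate)
  expect_error(powerlaw_fit(rep(0, 10)), "zero")
  expect_error(powerlaw_fit(c(1, 2, 3)), "at least 5")
})

test_that("motif census isolates a single cyclic triad", {
  g <- igraph::graph_from_literal(a -+ b, b -+ c, c -+ a)
  mc <- motif_census(g, n_random = 5, seed = 1)
  expect_equal(mc$observed[mc$class == "030C"], 1)
  expect_equal(sum(mc$observed), 1)
})

test_that("motif census totals match exhaustive triple enumeration", {
  set.seed(77)
  for (n in 6:7) for (i in 1:10) {
    adj <- random_adj(n, 0.35)
    mc <- motif_census(adj_to_igraph(adj), n_random = 2, seed = 1)
    ref <- bf_triad_counts(adj)
    # disconnected canonical codes: empty (0), single edge (1), mutual (5)
    conn_total <- sum(unlist(ref[setdiff(names(ref), c("0", "1", "5"))]))
    expect_equal(sum(mc$observed), conn_total)
    # the cyclic triad class has a unique canonical code: check it by name
    code_030C <- as.character(min(sum(c(1, 0, 0, 1, 1, 0) * 2^(0:5)),
                                  sum(c(0, 1, 1, 0, 0, 1) * 2^(0:5))))
    expect_equal(mc$observed[mc$class == "030C"],
                 if (is.null(ref[[code_030C]])) 0 else ref[[code_030C]])
  }
})
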