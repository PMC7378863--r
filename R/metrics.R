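# Coerce the objects analytics accept (interaction_network or igraph) to a
# directed igraph graph.
to_graph <- function(x) {
  g <- if (inherits(x, "interaction_network")) network_graph(x)
    else if (igraph::is_igraph(x)) x
    else stopf("expected an `interaction_network` or an igraph graph")
  if (!("name" %in% igraph::vertex_attr_names(g)))
    igraph::V(g)$name <- sprintf("v%04d", seq_len(igraph::vcount(g)))
  g
}

# Undirected projection: antiparallel pairs collapse to one edge; all edge
# attributes dropped so nothing downstream treats weights as capacities.
undirected_projection <- function(g) {
  und <- igraph::as_undirected(g, mode = "collapse")
  for (a in igraph::edge_attr_names(und))
    und <- igraph::delete_edge_attr(und, a)
  und
}

#' Newman modularity of a partition
#'
#' Direct evaluation of `Q = (1/2m) sum_ij (A_ij - k_i k_j / 2m) delta(c_i, c_j)`
#' on the unweighted undirected projection; an edgeless graph has `Q = 0` by
#' convention.
#'
#' @param net network or igraph graph.
#' @param membership named integer vector, one module id per node.
#' @return The modularity value.
#' @export
newman_modularity <- function(net, membership) {
  und <- undirected_projection(to_graph(net))
  m <- igraph::ecount(und)
  if (m == 0) return(0)
  A <- igraph::as_adjacency_matrix(und, sparse = FALSE)
  memb <- membership[igraph::V(und)$name]
  k <- rowSums(A)
  same <- outer(memb, memb, "==")
  sum((A - outer(k, k) / (2 * m)) * same) / (2 * m)
}

#' Greedy agglomerative community detection
#'
#' Clauset-Newman-Moore style greedy modularity maximization on the
#' unweighted undirected projection: starting from singleton modules, the
#' merge with the largest modularity gain is applied until no merge
#' improves modularity. Ties are broken deterministically by merging the
#' pair whose (lexicographically smallest) representative node labels sort
#' first. Each node of an edgeless graph is its own module with modularity
#' 0 by convention.
#'
#' @param net network or igraph graph.
#' @return List with `membership` (named integer vector, modules numbered
#'   by first appearance), `modularity`, `n_modules`, `module_sizes`.
#' @export
detect_communities <- function(net) {
  und <- undirected_projection(to_graph(net))
  n <- as.integer(igraph::vcount(und))
  if (n == 0) stopf("graph has no nodes")
  nodes <- igraph::V(und)$name
  m <- igraph::ecount(und)
  if (m == 0) {
    memb <- setNames(seq_len(n), nodes)
    return(list(membership = memb, modularity = 0, n_modules = n,
                module_sizes = rep(1L, n)))
  }
  A <- igraph::as_adjacency_matrix(und, sparse = FALSE)
  comm <- as.list(seq_len(n))                 # node indices per community
  L <- A / 1                                  # inter-community edge counts
  diag(L) <- 0                                # simple graph: no intra edges yet
  intra <- rep(0, n)
  d <- rowSums(A)                             # community degree sums
  repeat {
    if (length(comm) < 2) break
    gain <- L / m - outer(d, d) / (2 * m^2)
    gain[L == 0] <- -Inf                      # only merge connected pairs
    gain[lower.tri(gain, diag = TRUE)] <- -Inf
    best <- max(gain)
    if (best <= 1e-12) break
    cand <- which(gain >= best - 1e-12, arr.ind = TRUE)
    if (nrow(cand) > 1) {
      reps <- t(apply(cand, 1, function(rc) {
        sort(c(min(nodes[comm[[rc[1]]]]), min(nodes[comm[[rc[2]]]])))
      }))
      cand <- cand[order(reps[, 1], reps[, 2]), , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    comm[[i]] <- c(comm[[i]], comm[[j]]); comm[[j]] <- NULL
    intra[i] <- intra[i] + intra[j] + L[i, j]; intra <- intra[-j]
    d[i] <- d[i] + d[j]; d <- d[-j]
    L[i, ] <- L[i, ] + L[j, ]; L[, i] <- L[, i] + L[, j]
    L <- L[-j, -j, drop = FALSE]
    diag(L) <- 0
  }
  memb <- integer(n)
  ord <- order(vapply(comm, min, 0L))          # number modules by first node
  for (k in seq_along(ord)) memb[comm[[ord[k]]]] <- k
  memb <- setNames(memb, nodes)
  list(membership = memb,
       modularity = sum(intra) / m - sum((d / (2 * m))^2),
       n_modules = length(comm),
       module_sizes = as.integer(table(memb)))
}

# Deterministic greedy maximal independent set on the undirected projection:
# visit nodes by ascending total degree (ties by label), add when no
# neighbour is already in the set.
greedy_independent_set <- function(und) {
  n <- igraph::vcount(und)
  if (n == 0) return(character(0))
  nodes <- igraph::V(und)$name
  deg <- igraph::degree(und)
  ord <- order(deg, nodes)
  in_set <- logical(n)
  blocked <- logical(n)
  adj <- igraph::as_adj_list(und)
  for (v in ord) {
    if (blocked[v]) next
    in_set[v] <- TRUE
    blocked[as.integer(adj[[v]])] <- TRUE
  }
  sort(nodes[in_set])
}

#' Discrete power-law fit of a degree distribution
#'
#' Maximum-likelihood exponent of `P(k) ~ k^(-alpha)` for `k >= 1` (zeta
#' normalization, `xmin = 1`), with the Kolmogorov-Smirnov distance between
#' the empirical and fitted CDFs over the observed support. Zero degrees
#' are excluded before fitting.
#'
#' @param degrees integer degree vector with at least 5 nonzero entries.
#' @return List with `alpha`, `ks`, `n` (nonzero degrees used), and
#'   `degenerate` (`TRUE`, with a warning, when all degrees are equal).
#' @export
powerlaw_fit <- function(degrees) {
  x <- degrees[degrees > 0]
  if (!length(x)) stopf("all degrees are zero")
  if (length(x) < 5) stopf("need at least 5 nonzero degrees")
  degenerate <- length(unique(x)) == 1L
  if (degenerate)
    warning("all degrees equal: power-law exponent is poorly identified",
            call. = FALSE)
  slx <- sum(log(x))
  nll <- function(a) length(x) * log(pracma::zeta(a)) + a * slx
  opt <- optimize(nll, c(1.001, 25))
  alpha <- opt$minimum
  ks_max <- max(x)
  fitted_cdf <- cumsum((1:ks_max)^(-alpha)) / pracma::zeta(alpha)
  emp_cdf <- vapply(1:ks_max, function(k) mean(x <= k), 0)
  list(alpha = alpha, ks = max(abs(emp_cdf - fitted_cdf)),
       n = length(x), degenerate = degenerate)
}

#' Full network property report
#'
#' Computes the standard descriptive property vector of a directed
#' interaction network. Density is `size / (order * (order - 1))`; the mean
#' degree is reported both in the directed convention `size / order` and as
#' the total-degree mean `2 * size / order`. Clustering (average local
#' coefficient, isolated and degree-1 nodes counting 0), diameter, radius,
#' minimum cuts, the maximal independent set and communities are computed
#' on the undirected projection (antiparallel edge pairs collapse to one
#' edge); diameter, radius and cuts refer to its largest connected
#' component. Cycles are summarized through strongly connected components
#' of size >= 2. The degree distribution is fitted by [powerlaw_fit()].
#'
#' @param net an `interaction_network` or a directed igraph graph.
#' @param cut_sets also report one deterministic minimum vertex/edge cut
#'   set of the largest component (connectivity numbers are always
#'   reported).
#' @param powerlaw fit the total-degree distribution (skipped, with `NA`
#'   results, when fewer than 5 nonzero degrees are available).
#' @return An object of class `network_report`: a named list of properties.
#' @export
network_metrics <- function(net, cut_sets = TRUE, powerlaw = TRUE) {
  g <- to_graph(net)
  n <- igraph::vcount(g)
  if (n == 0) stopf("graph has no nodes")
  m <- igraph::ecount(g)
  und <- undirected_projection(g)

  comp <- igraph::components(g, mode = "weak")
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(und, which(comp$membership == big))

  scc <- igraph::components(g, mode = "strong")
  n_cyclic <- sum(scc$csize[scc$csize >= 2])

  comms <- detect_communities(und)
  mis <- greedy_independent_set(und)

  deg_total <- igraph::degree(g, mode = "all")
  pl <- list(alpha = NA_real_, ks = NA_real_, degenerate = NA)
  if (powerlaw && sum(deg_total > 0) >= 5)
    pl <- suppressWarnings(powerlaw_fit(deg_total))

  vc <- if (igraph::vcount(sub) > 1) igraph::vertex_connectivity(sub) else 0
  ec <- if (igraph::vcount(sub) > 1) igraph::edge_connectivity(sub) else 0
  vertex_cut <- character(0); edge_cut <- character(0)
  if (cut_sets && igraph::vcount(sub) > 1) {
    cutinfo <- igraph::min_cut(sub, value.only = FALSE)
    ends <- igraph::ends(sub, cutinfo$cut)
    edge_cut <- sort(paste(pmin(ends[, 1], ends[, 2]),
                           pmax(ends[, 1], ends[, 2]), sep = "--"))
    if (vc < igraph::vcount(sub) - 1) {      # complete graphs have no separator
      seps <- igraph::min_separators(sub)
      sets <- lapply(seps, function(s) sort(igraph::V(sub)$name[as.integer(s)]))
      keys <- vapply(sets, paste, "", collapse = "|")
      vertex_cut <- sets[[order(keys)[1]]]
    }
  }

  structure(list(
    order = n,
    size = m,
    density = if (n > 1) m / (n * (n - 1)) else 0,
    mean_degree = m / n,
    mean_total_degree = 2 * m / n,
    clustering = igraph::transitivity(und, type = "average", isolates = "zero"),
    diameter = if (igraph::vcount(sub) > 1)
      igraph::diameter(sub, weights = NA) else 0,
    radius = if (igraph::vcount(sub) > 1) igraph::radius(sub) else 0,
    n_components = comp$no,
    largest_component_size = max(comp$csize),
    has_cycles = n_cyclic > 0,
    n_cyclic_nodes = n_cyclic,
    independent_set = mis,
    independent_set_size = length(mis),
    vertex_connectivity = vc,
    edge_connectivity = ec,
    vertex_cut = vertex_cut,
    edge_cut = edge_cut,
    modularity = comms$modularity,
    n_modules = comms$n_modules,
    communities = comms$membership,
    max_total_degree = if (n > 0) max(deg_total) else 0,
    max_in_degree = max(igraph::degree(g, mode = "in")),
    max_out_degree = max(igraph::degree(g, mode = "out")),
    powerlaw_alpha = pl$alpha,
    powerlaw_ks = pl$ks
  ), class = "network_report")
}

#' @export
print.network_report <- function(x, ...) {
  cat("network property report\n")
  cat(sprintf("  order %d, size %d, density %.4f, mean degree %.3f (total %.3f)\n",
              x$order, x$size, x$density, x$mean_degree, x$mean_total_degree))
  cat(sprintf("  clustering %.4f, diameter %d, radius %d, components %d\n",
              x$clustering, x$diameter, x$radius, x$n_components))
  cat(sprintf("  modularity %.4f over %d modules; %d cyclic nodes; MIS size %d\n",
              x$modularity, x$n_modules, x$n_cyclic_nodes, x$independent_set_size))
  if (is.finite(x$powerlaw_alpha))
    cat(sprintf("  degree power-law alpha %.3f (KS %.3f)\n",
                x$powerlaw_alpha, x$powerlaw_ks))
  invisible(x)
}

# Length-1 numeric view of a report, used for null-model comparison.
report_numeric <- function(report) {
  keep <- vapply(report, function(v)
    is.numeric(v) && length(v) == 1L, TRUE)
  unlist(report[keep])
}

#' Identify hub (keystone candidate) taxa
#'
#' Returns the node sets achieving the maximal total, in- and out-degree
#' (self-loops excluded; ties return every maximizer, sorted by label),
#' together with the maxima themselves.
#'
#' @param net network or directed igraph graph with at least one node.
#' @return An object of class `hub_report`.
#' @export
identify_hubs <- function(net) {
  g <- to_graph(net)
  if (igraph::vcount(g) == 0) stopf("graph has no nodes")
  g <- igraph::simplify(g, remove.multiple = FALSE, remove.loops = TRUE)
  hub_set <- function(mode) {
    deg <- igraph::degree(g, mode = mode)
    mx <- max(deg)
    list(set = sort(names(deg)[deg == mx]), max = mx)
  }
  tot <- hub_set("all"); inn <- hub_set("in"); out <- hub_set("out")
  structure(list(hubs_total = tot$set, max_total = tot$max,
                 hubs_in = inn$set, max_in = inn$max,
                 hubs_out = out$set, max_out = out$max),
            class = "hub_report")
}

#' @export
print.hub_report <- function(x, ...) {
  cat(sprintf("hubs: total degree %d (%s); in %d (%s); out %d (%s)\n",
              x$max_total, paste(x$hubs_total, collapse = ", "),
              x$max_in, paste(x$hubs_in, collapse = ", "),
              x$max_out, paste(x$hubs_out, collapse = ", ")))
  invisible(x)
}

triad_classes <- c("021D", "021U", "021C", "111D", "111U", "030T", "030C",
                   "201", "120D", "120U", "120C", "210", "300")

#' Three-node motif census with degree-preserving null
#'
#' Counts the 13 connected directed triad isomorphism classes
#' ([igraph::triad_census()] order, disconnected classes dropped) and
#' compares each count to `n_random` degree-preserving edge-switch
#' randomizations (10 switches per edge per replicate). The z-score is
#' `(observed - null mean) / null sd`, reported as `NA` where the null has
#' zero spread.
#'
#' @param net network or directed igraph graph with >= 3 nodes.
#' @param n_random number of randomized replicates.
#' @param seed optional integer seed.
#' @return data.frame with columns `class`, `observed`, `null_mean`,
#'   `null_sd`, `z`.
#' @export
motif_census <- function(net, n_random = 100, seed = NULL) {
  g <- to_graph(net)
  if (igraph::vcount(g) < 3) stopf("motif census needs at least 3 nodes")
  obs <- igraph::triad_census(g)[4:16]
  m <- igraph::ecount(g)
  with_seed(seed, {
    nulls <- matrix(NA_real_, n_random, 13)
    for (r in seq_len(n_random)) {
      gr <- if (m >= 2)
        igraph::rewire(g, igraph::keeping_degseq(loops = FALSE, niter = 10 * m))
      else g
      nulls[r, ] <- igraph::triad_census(gr)[4:16]
    }
    mu <- colMeans(nulls); sdev <- apply(nulls, 2, sd)
    data.frame(class = triad_classes, observed = as.numeric(obs),
               null_mean = mu, null_sd = sdev,
               z = ifelse(sdev > 0, (obs - mu) / sdev, NA_real_),
               stringsAsFactors = FALSE)
  })
}
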