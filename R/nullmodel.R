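#' Random ensemble matched on order and size
#'
#' Draws `n` directed graphs uniformly from the simple directed graphs
#' (no self-loops) with exactly `order` nodes and `size` edges — the
#' Erdos-Renyi G(n, m) family, the minimal null matching a network's order
#' and size.
#'
#' @param order node count.
#' @param size edge count; at most `order * (order - 1)`.
#' @param n ensemble size (default 100).
#' @param seed optional integer seed.
#' @return List of `n` directed igraph graphs.
#' @export
random_ensemble <- function(order, size, n = 100, seed = NULL) {
  if (order < 1) stopf("`order` must be >= 1")
  max_m <- order * (order - 1)
  if (size < 0 || size > max_m)
    stopf("`size` must lie in [0, %d] for %d nodes", max_m, order)
  with_seed(seed, {
    lapply(seq_len(n), function(i)
      igraph::sample_gnm(order, size, directed = TRUE))
  })
}

#' Compare an observed property report to a null ensemble
#'
#' For every scalar numeric property of the observed report, computes the
#' ensemble mean and SD and an add-one empirical two-sided p-value:
#' `p = min(1, 2 * min(p_low, p_high))` with
#' `p_low = (1 + #\{null <= obs\}) / (N + 1)` (and symmetrically for
#' `p_high`), so both deficits and excesses relative to random graphs are
#' flagged and p can never be exactly zero. Properties matched by
#' construction (order, size, density) come out non-significant
#' automatically.
#'
#' @param observed a [network_metrics()] report.
#' @param ensemble list of `network_report`s, or list of igraph graphs
#'   (reports are then computed with `cut_sets = FALSE`).
#' @param alpha significance level.
#' @return An object of class `null_summary`: data.frame with columns
#'   `property`, `observed`, `null_mean`, `null_sd`, `n_null`, `p`,
#'   `significant`.
#' @export
compare_to_null <- function(observed, ensemble, alpha = 0.05) {
  if (!length(ensemble)) stopf("ensemble is empty")
  if (igraph::is_igraph(ensemble[[1]]))
    ensemble <- lapply(ensemble, network_metrics, cut_sets = FALSE)
  obs <- report_numeric(observed)
  null_mat <- vapply(ensemble, function(rep) {
    v <- report_numeric(rep)
    if (!all(names(obs) %in% names(v)))
      stopf("ensemble report lacks propert%s: %s",
            if (sum(!names(obs) %in% names(v)) > 1) "ies" else "y",
            paste(setdiff(names(obs), names(v)), collapse = ", "))
    v[names(obs)]
  }, obs)
  rows <- lapply(names(obs), function(pr) {
    nulls <- null_mat[pr, ]
    nulls <- nulls[!is.na(nulls)]
    N <- length(nulls)
    if (N == 0 || is.na(obs[[pr]])) {
      p <- NA_real_
    } else {
      p_low <- (1 + sum(nulls <= obs[[pr]])) / (N + 1)
      p_high <- (1 + sum(nulls >= obs[[pr]])) / (N + 1)
      p <- min(1, 2 * min(p_low, p_high))
    }
    data.frame(property = pr, observed = obs[[pr]],
               null_mean = if (N) mean(nulls) else NA_real_,
               null_sd = if (N) sd(nulls) else NA_real_,
               n_null = N, p = p,
               significant = if (is.na(p)) NA else p <= alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  class(out) <- c("null_summary", "data.frame")
  out
}

#' @export
print.null_summary <- function(x, ...) {
  cat(sprintf("null-model comparison (N = %d, alpha = %.3g)\n",
              max(x$n_null), attr(x, "alpha")))
  df <- as.data.frame(x)
  df$observed <- signif(df$observed, 4)
  df$null_mean <- signif(df$null_mean, 4)
  df$null_sd <- signif(df$null_sd, 3)
  df$p <- signif(df$p, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' One-call null-model significance test for a network
#'
#' Builds the matched G(n, m) ensemble for the network's order and size,
#' computes property reports for the observed network and every ensemble
#' member under identical settings, and summarizes with
#' [compare_to_null()].
#'
#' @param net an `interaction_network` or directed igraph graph.
#' @param n ensemble size (default one hundred).
#' @param alpha significance level.
#' @param seed optional integer seed.
#' @param cut_sets,powerlaw forwarded to [network_metrics()].
#' @return A `null_summary` with the ensemble stored in attribute
#'   `"ensemble_size"`.
#' @export
null_model_test <- function(net, n = 100, alpha = 0.05, seed = NULL,
                            cut_sets = FALSE, powerlaw = TRUE) {
  g <- to_graph(net)
  observed <- network_metrics(g, cut_sets = cut_sets, powerlaw = powerlaw)
  graphs <- random_ensemble(igraph::vcount(g), igraph::ecount(g),
                            n = n, seed = seed)
  reports <- lapply(graphs, network_metrics,
                    cut_sets = cut_sets, powerlaw = powerlaw)
  out <- compare_to_null(observed, reports, alpha = alpha)
  attr(out, "ensemble_size") <- n
  out
}
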