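#' Configuration for consensus network inference
#'
#' @param pseudocount value substituted for zero proportions before taking
#'   logs; `NULL` (default) uses half the smallest nonzero proportion of the
#'   input table.
#' @param n_orderings number of sample orderings `B` over which the
#'   consensus is taken. Ordering 1 is always the canonical
#'   (season, site, replicate) order; further orderings permute samples
#'   within each season block, preserving the dry-to-rainy direction. The
#'   default `1` fits the canonical ordering only: at survey-scale sample
#'   sizes sparse selection is unstable under reordering, so multi-ordering
#'   consensus is a stability analysis (edge weights become selection
#'   stability), not the default estimator.
#' @param consensus_threshold minimum fraction `f` of orderings that must
#'   select an interaction with a consistent sign for it to enter the
#'   consensus network, in (0, 1].
#' @param max_parents cap on the number of interactors selected per target
#'   taxon.
#' @param criterion information criterion guiding forward selection.
#' @param prune if `TRUE` (default), a backward-elimination pass removes
#'   selected predictors whose deletion improves the criterion.
#' @return An object of class `glv_config`.
#' @export
glv_config <- function(pseudocount = NULL, n_orderings = 1,
                       consensus_threshold = 1, max_parents = 5,
                       criterion = c("bic", "aic"), prune = TRUE) {
  criterion <- match.arg(criterion)
  if (!is.null(pseudocount) && pseudocount <= 0) stopf("`pseudocount` must be > 0")
  if (n_orderings < 1) stopf("`n_orderings` must be >= 1")
  if (consensus_threshold <= 0 || consensus_threshold > 1)
    stopf("`consensus_threshold` must lie in (0, 1]")
  structure(list(pseudocount = pseudocount,
                 n_orderings = as.integer(n_orderings),
                 consensus_threshold = consensus_threshold,
                 max_parents = as.integer(max_parents),
                 criterion = criterion, prune = prune),
            class = "glv_config")
}

#' Build the gLV regression design from an ordered abundance series
#'
#' Linearizes the Ricker-type gLV update on log-ratios: for consecutive
#' samples `t` and `t+1` the response of taxon `i` is
#' `y_i(t) = log x_i(t+1) - log x_i(t)` and the predictors are the
#' abundances `x_j(t)` of all taxa (the intercept carries the intrinsic
#' growth rate). Zeros are replaced by `pseudocount` before logs. A list of
#' matrices is treated as independent ordered segments (e.g. restarted
#' trajectories or per-condition series) whose transition rows are stacked;
#' no transition spans a segment boundary.
#'
#' @param series taxa x samples numeric matrix ordered in (pseudo-)time, or
#'   a list of such matrices sharing the same taxa.
#' @param pseudocount replacement for zero values (`NULL`: half the smallest
#'   nonzero value across the series).
#' @return List with `response` (`T x n` matrix of log-ratios, one column
#'   per taxon), `design` (`T x n` matrix of predecessor abundances),
#'   `taxa`, and the `pseudocount` used.
#' @export
build_design <- function(series, pseudocount = NULL) {
  segs <- if (is.list(series)) series else list(series)
  taxa <- rownames(segs[[1]])
  if (sum(vapply(segs, ncol, 0L)) < 3) stopf("need at least 3 ordered samples")
  for (s in segs) {
    if (ncol(s) < 2) stopf("every segment needs at least 2 ordered samples")
    if (any(s < 0)) stopf("abundances must be >= 0")
  }
  if (is.null(pseudocount)) {
    nz <- unlist(lapply(segs, function(s) s[s > 0]))
    if (!length(nz)) stopf("series is identically zero")
    pseudocount <- min(nz) / 2
  }
  resp <- NULL; des <- NULL
  for (s in segs) {
    s[s == 0] <- pseudocount
    lg <- log(s)
    resp <- rbind(resp, t(lg[, -1, drop = FALSE] - lg[, -ncol(s), drop = FALSE]))
    des <- rbind(des, t(s[, -ncol(s), drop = FALSE]))
  }
  colnames(resp) <- taxa; colnames(des) <- taxa
  rownames(resp) <- NULL; rownames(des) <- NULL
  list(response = resp, design = des, taxa = taxa, pseudocount = pseudocount)
}

ic_of <- function(rss, n_par, n_obs, criterion) {
  pen <- if (criterion == "bic") log(n_obs) else 2
  # floor keeps an exact fit finite while still separated by the penalty
  n_obs * log(max(rss, 1e-300) / n_obs) + pen * n_par
}

#' Sparse per-taxon gLV fit by forward selection
#'
#' Starting from the intercept-only model, greedily adds the predictor
#' column that most improves the information criterion (ordinary least
#' squares at every step; ties broken by the lowest column index), stopping
#' when no addition improves it or `max_parents` is reached; an optional
#' backward pass then drops predictors whose removal improves the
#' criterion. Constant (zero-variance) columns are skipped with a warning.
#'
#' @param y response vector (one taxon's log-ratios).
#' @param design predictor matrix from [build_design()].
#' @param config a [glv_config()].
#' @return List with `coefficients` (full-length named vector, zero for
#'   unselected taxa), `intercept` (the estimated intrinsic growth rate),
#'   `selected` (column indices in selection order) and `criterion` value.
#' @export
fit_taxon <- function(y, design, config = glv_config()) {
  n_obs <- length(y)
  if (nrow(design) != n_obs) stopf("`y` and `design` row counts differ")
  p <- ncol(design)
  const <- apply(design, 2, function(z) max(z) - min(z) < 1e-12)
  if (any(const))
    warning(sprintf("skipping constant design column(s): %s",
                    paste(colnames(design)[const], collapse = ", ")),
            call. = FALSE)
  sel <- integer(0)
  Q <- matrix(1 / sqrt(n_obs), n_obs, 1)          # orthonormal basis incl. intercept
  res <- y - Q %*% crossprod(Q, y)
  rss <- sum(res^2)
  ic <- ic_of(rss, 2, n_obs, config$criterion)    # intercept + variance
  repeat {
    cand <- setdiff(which(!const), sel)
    if (!length(cand) || length(sel) >= config$max_parents) break
    Z <- design[, cand, drop = FALSE]
    Z <- Z - Q %*% crossprod(Q, Z)
    den <- colSums(Z^2)
    num <- drop(crossprod(Z, res))^2
    gain <- ifelse(den > 1e-10 * n_obs, num / den, -Inf)
    ic_new <- vapply(pmax(rss - gain, 0), ic_of,
                     0, n_par = length(sel) + 3, n_obs = n_obs,
                     criterion = config$criterion)
    j <- which.min(ic_new)                         # ties -> lowest index
    if (!is.finite(gain[j]) || ic_new[j] >= ic - 1e-9) break
    sel <- c(sel, cand[j])
    z <- Z[, j] / sqrt(den[j])
    Q <- cbind(Q, z)
    res <- res - z * sum(z * res)
    rss <- max(rss - gain[j], 0)
    ic <- ic_new[j]
  }
  if (config$prune) {
    repeat {
      if (length(sel) < 2) break
      improved <- FALSE
      for (d in seq_along(sel)) {
        s2 <- sel[-d]
        f2 <- lm.fit(cbind(1, design[, s2, drop = FALSE]), y)
        ic2 <- ic_of(sum(f2$residuals^2), length(s2) + 2, n_obs, config$criterion)
        if (ic2 < ic - 1e-9) { sel <- s2; ic <- ic2; improved <- TRUE; break }
      }
      if (!improved) break
    }
  }
  co <- setNames(numeric(p), colnames(design))
  intercept <- mean(y)
  if (length(sel)) {
    fit <- lm.fit(cbind(1, design[, sel, drop = FALSE]), y)
    co[sel] <- fit$coefficients[-1]
    intercept <- fit$coefficients[1]
  }
  list(coefficients = co, intercept = intercept,
       selected = sel, criterion = ic)
}

# Canonical sample order: by season (level order of the metadata factor or
# first-appearance order), then site, then replicate.
canonical_order <- function(samples, metadata) {
  idx <- match(samples, metadata$sample_id)
  md <- metadata[idx, , drop = FALSE]
  season <- if ("season" %in% names(md))
    match(md$season, unique(metadata$season)) else rep(1L, nrow(md))
  site <- if ("site" %in% names(md)) md$site else seq_len(nrow(md))
  repl <- if ("replicate" %in% names(md)) md$replicate else seq_len(nrow(md))
  samples[order(season, site, repl)]
}

#' Infer a directed signed consensus interaction network
#'
#' The central fitting function: repeats the log-ratio gLV regression
#' ([build_design()] + [fit_taxon()]) over `n_orderings` sample orderings
#' and keeps a directed interaction `j -> i` (taxon j affects taxon i) only
#' if it is selected with a consistent sign in at least
#' `consensus_threshold * n_orderings` of them. Edge weight is that support
#' fraction; the reported coefficient is the median over supporting fits.
#' Self-effects (the diagonal of the interaction matrix) are estimated the
#' same way but kept out of the edge list, which analytics treat as a
#' simple directed graph.
#'
#' For survey data the first ordering is the canonical (season, site,
#' replicate) order and the rest permute samples within season blocks,
#' preserving the dry-to-rainy direction; with `time_series = TRUE` the
#' given column order is used for every ordering instead.
#'
#' @param x taxa x samples matrix of relative abundances (any non-negative
#'   abundance works; proportions are the standard input).
#' @param metadata optional data.frame with `sample_id` and the design
#'   columns `soil_type`, `season`, `site`, `replicate`.
#' @param subset optional named character vector restricting samples, e.g.
#'   `c(soil_type = "rhizosphere", season = "dry")`.
#' @param config a [glv_config()].
#' @param time_series treat columns as already ordered in time.
#' @param seed optional integer seed for the ordering draws.
#' @return An object of class `interaction_network`: list with `nodes`
#'   (taxa incident to at least one consensus edge), `edges` (data.frame
#'   `source`, `target`, `sign`, `weight`, `coefficient`), `self_effects`,
#'   `growth_rates` (median intercepts), `taxa` (all taxa offered to the
#'   regression), `config`, `subset`, `n_samples`.
#' @examples
#' p <- sample_glv_parameters(5, connectance = 0.2, seed = 4)
#' tr <- simulate_glv(p, runif(5, 0.5, 2), steps = 12)
#' net <- infer_network(tr$abundances, time_series = TRUE,
#'                      config = glv_config(n_orderings = 1,
#'                                          consensus_threshold = 1))
#' net
#' @export
infer_network <- function(x, metadata = NULL, subset = NULL,
                          config = glv_config(), time_series = FALSE,
                          seed = NULL) {
  if (!is.null(subset)) {
    if (is.null(metadata)) stopf("`subset` requires `metadata`")
    keep <- rep(TRUE, nrow(metadata))
    for (f in names(subset)) keep <- keep & metadata[[f]] == subset[[f]]
    samples <- intersect(colnames(x), metadata$sample_id[keep])
    x <- x[, samples, drop = FALSE]
  }
  if (ncol(x) < 4) stopf("need at least 4 samples in the selected subset")
  if (is.null(colnames(x))) colnames(x) <- sprintf("s%03d", seq_len(ncol(x)))
  x <- x[rowSums(x) > 0, , drop = FALSE]
  if (nrow(x) == 0) stopf("no taxa left after removing empty rows")
  taxa <- rownames(x)
  n <- length(taxa)
  B <- config$n_orderings

  base_order <- if (time_series || is.null(metadata)) colnames(x)
    else canonical_order(colnames(x), metadata)
  season_of <- if (!time_series && !is.null(metadata) && "season" %in% names(metadata))
    metadata$season[match(base_order, metadata$sample_id)]
    else rep("all", length(base_order))

  with_seed(seed, {
    n_pos <- matrix(0L, n, n); n_neg <- matrix(0L, n, n)
    coefs <- vector("list", B)
    intercepts <- matrix(NA_real_, B, n)
    for (b in seq_len(B)) {
      ord <- if (b == 1L || time_series) base_order
        else unlist(lapply(split(base_order, factor(season_of, unique(season_of))),
                           function(s) s[sample.int(length(s))]),
                    use.names = FALSE)
      segs <- split(ord, factor(season_of, unique(season_of)))
      segs <- segs[vapply(segs, length, 0L) >= 2]
      d <- build_design(lapply(segs, function(s) x[, s, drop = FALSE]),
                        pseudocount = config$pseudocount)
      Ab <- matrix(0, n, n, dimnames = list(taxa, taxa))
      for (i in seq_len(n)) {
        fit <- suppressWarnings(fit_taxon(d$response[, i], d$design, config))
        Ab[i, ] <- fit$coefficients
        intercepts[b, i] <- fit$intercept
      }
      n_pos <- n_pos + (Ab > 0)
      n_neg <- n_neg + (Ab < 0)
      coefs[[b]] <- Ab
    }
    need <- config$consensus_threshold * B - 1e-9
    support <- pmax(n_pos, n_neg)
    hit <- which(support >= need, arr.ind = TRUE)
    edges <- data.frame(source = character(0), target = character(0),
                        sign = integer(0), weight = numeric(0),
                        coefficient = numeric(0), stringsAsFactors = FALSE)
    selfs <- edges
    if (nrow(hit)) {
      rows <- lapply(seq_len(nrow(hit)), function(k) {
        i <- hit[k, 1]; j <- hit[k, 2]
        sgn <- if (n_pos[i, j] >= n_neg[i, j]) 1L else -1L
        vals <- vapply(coefs, function(A) A[i, j], 0)
        vals <- vals[sign(vals) == sgn]
        data.frame(source = taxa[j], target = taxa[i], sign = sgn,
                   weight = support[i, j] / B, coefficient = median(vals),
                   stringsAsFactors = FALSE)
      })
      all_rows <- do.call(rbind, rows)
      is_self <- all_rows$source == all_rows$target
      selfs <- all_rows[is_self, , drop = FALSE]
      edges <- all_rows[!is_self, , drop = FALSE]
      edges <- edges[order(edges$source, edges$target), , drop = FALSE]
      rownames(edges) <- NULL
    }
    structure(
      list(nodes = sort(unique(c(edges$source, edges$target))),
           edges = edges,
           self_effects = data.frame(taxon = selfs$source,
                                     coefficient = selfs$coefficient,
                                     weight = selfs$weight,
                                     stringsAsFactors = FALSE),
           growth_rates = setNames(apply(intercepts, 2, median), taxa),
           taxa = taxa, config = config, subset = subset,
           n_samples = length(base_order), n_orderings = B),
      class = "interaction_network")
  })
}

#' Coerce an interaction network to an igraph graph
#'
#' @param net an `interaction_network`.
#' @param all_taxa include taxa without any consensus edge as isolated
#'   vertices.
#' @return A directed [igraph::igraph] graph with edge attributes `sign`,
#'   `weight`, `coefficient`.
#' @export
network_graph <- function(net, all_taxa = FALSE) {
  verts <- if (all_taxa) net$taxa else net$nodes
  igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                vertices = data.frame(name = verts))
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("consensus interaction network: %d nodes, %d edges (%d +, %d -)\n",
              length(x$nodes), nrow(x$edges),
              sum(x$edges$sign > 0), sum(x$edges$sign < 0)))
  if (!is.null(x$subset))
    cat("  subset:", paste(names(x$subset), unlist(x$subset),
                           sep = "=", collapse = ", "), "\n")
  cat(sprintf("  %d samples, %d orderings, consensus >= %.2f\n",
              x$n_samples, x$n_orderings, x$config$consensus_threshold))
  invisible(x)
}

#' @export
summary.interaction_network <- function(object, ...) {
  n <- length(object$nodes); m <- nrow(object$edges)
  hubs <- if (n > 0) identify_hubs(object) else NULL
  out <- list(order = n, size = m,
              positive = sum(object$edges$sign > 0),
              negative = sum(object$edges$sign < 0),
              density = if (n > 1) m / (n * (n - 1)) else NA_real_,
              hubs = hubs)
  class(out) <- "summary.interaction_network"
  out
}

#' @export
print.summary.interaction_network <- function(x, ...) {
  cat(sprintf("order %d, size %d (%d positive, %d negative), density %.4f\n",
              x$order, x$size, x$positive, x$negative, x$density))
  if (!is.null(x$hubs))
    cat(sprintf("hub (max total degree %d): %s\n", x$hubs$max_total,
                paste(x$hubs$hubs_total, collapse = ", ")))
  invisible(x)
}

#' @export
coef.interaction_network <- function(object, ...) {
  taxa <- object$taxa
  A <- matrix(0, length(taxa), length(taxa), dimnames = list(taxa, taxa))
  if (nrow(object$edges))
    A[cbind(match(object$edges$target, taxa),
            match(object$edges$source, taxa))] <- object$edges$coefficient
  if (nrow(object$self_effects))
    A[cbind(match(object$self_effects$taxon, taxa),
            match(object$self_effects$taxon, taxa))] <- object$self_effects$coefficient
  A
}

#' @export
plot.interaction_network <- function(x, ...) {
  g <- network_graph(x)
  igraph::plot.igraph(
    g,
    edge.color = ifelse(igraph::E(g)$sign > 0, "steelblue", "firebrick"),
    vertex.size = 4 + 2 * sqrt(igraph::degree(g)),
    vertex.label.cex = 0.6, edge.arrow.size = 0.3, ...)
  invisible(x)
}

#' Write / read a network edge list
#'
#' The TSV format has columns `source`, `target`, `sign`, `weight`,
#' `coefficient`; `format = "graphml"` writes GraphML via
#' [igraph::write_graph()].
#'
#' @param net an `interaction_network`.
#' @param path output file.
#' @param format `"tsv"` or `"graphml"`.
#' @return `write_network()`: the path, invisibly. `read_network()`: an
#'   `interaction_network` rebuilt from the edge list.
#' @export
write_network <- function(net, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(net$edges, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE)
  } else {
    igraph::write_graph(network_graph(net), path, format = "graphml")
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  edges <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  req <- c("source", "target", "sign", "weight", "coefficient")
  if (!all(req %in% names(edges)))
    stopf("edge list %s needs columns: %s", path, paste(req, collapse = ", "))
  nodes <- sort(unique(c(edges$source, edges$target)))
  structure(list(nodes = nodes, edges = edges,
                 self_effects = data.frame(taxon = character(0),
                                           coefficient = numeric(0),
                                           weight = numeric(0)),
                 growth_rates = NULL, taxa = nodes, config = NULL,
                 subset = NULL, n_samples = NA_integer_,
                 n_orderings = NA_integer_),
            class = "interaction_network")
}
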