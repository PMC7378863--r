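#' Read / write a taxa-by-samples count table
#'
#' Count tables are tab-separated with a header row of sample IDs and taxon
#' IDs in the first column. Cells must be non-negative integers; violations
#' are reported with their row/column coordinates.
#'
#' @param path file path.
#' @return `read_count_table()`: an integer matrix (taxa x samples) with
#'   taxon rownames and sample colnames.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stopf("count table not found: %s", path)
  raw <- read.delim(path, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stopf("count table %s has no sample columns", path)
  header <- scan(path, what = "", sep = "\t", nlines = 1, quiet = TRUE)
  samples <- header[-1]
  if (anyDuplicated(samples))
    stopf("duplicated sample column in %s: %s", path,
          paste(unique(samples[duplicated(samples)]), collapse = ", "))
  taxa <- as.character(raw[[1]])
  if (anyDuplicated(taxa))
    stopf("duplicated taxon ID in %s: %s", path,
          paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(raw[, -1, drop = FALSE], 2, as.numeric))),
                 arr.ind = TRUE)[1, ]
    stopf("non-numeric count at row %d (taxon %s), column %s",
          bad[1], taxa[bad[1]], samples[bad[2]])
  }
  bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stopf("negative or non-integer count at row %d (taxon %s), column %s",
          bad[1, 1], taxa[bad[1, 1]], samples[bad[1, 2]])
  storage.mode(m) <- "integer"
  dimnames(m) <- list(taxa, samples)
  m
}

#' @param counts integer matrix, taxa x samples, with dimnames.
#' @rdname read_count_table
#' @return `write_count_table()`: the path, invisibly.
#' @export
write_count_table <- function(counts, path) {
  check_count_matrix(counts)
  df <- data.frame(taxon_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Rarefy libraries to a common depth
#'
#' Subsamples every library without replacement (hypergeometric draw, via
#' [vegan::rrarefy()]) to `depth` reads, the standard correction for unequal
#' sequencing effort. The default depth is the smallest library, so no
#' sample is discarded.
#'
#' @param counts taxa x samples integer matrix.
#' @param depth target depth; must not exceed any library size.
#' @param seed optional integer seed (fixed seed gives identical output).
#' @return Integer matrix of the same shape; every column sums to `depth`.
#' @export
rarefy <- function(counts, depth = min(colSums(counts)), seed = NULL) {
  check_count_matrix(counts)
  totals <- colSums(counts)
  low <- totals < depth
  if (any(low))
    stopf("depth %d exceeds library size of sample(s): %s",
          depth, paste(colnames(counts)[low], collapse = ", "))
  with_seed(seed, {
    # rrarefy's "observed counts" heuristic warning is spurious here: the
    # preconditions above already guarantee integer libraries >= depth
    out <- t(suppressWarnings(vegan::rrarefy(t(counts), depth)))
    storage.mode(out) <- "integer"
    dimnames(out) <- dimnames(counts)
    out
  })
}

#' Convert counts to relative abundances
#'
#' @param counts taxa x samples matrix with positive column totals.
#' @return Matrix of proportions; every column sums to 1.
#' @export
relative_abundance <- function(counts) {
  totals <- colSums(counts)
  if (any(totals <= 0))
    stopf("all-zero sample column(s): %s",
          paste(colnames(counts)[totals <= 0], collapse = ", "))
  sweep(counts, 2, totals, "/")
}

#' Filter taxa by taxonomic-assignment bootstrap confidence
#'
#' Keeps taxa classified at `rank` with bootstrap confidence `>= min_conf`
#' (inclusive), the usual cutoff being 80%. Returns the filtered table plus
#' a report of what was discarded, including the fraction of total reads
#' removed.
#'
#' @param counts taxa x samples matrix.
#' @param taxonomy data.frame with `taxon_id` and a `<rank>_conf` column of
#'   confidences in `[0, 1]`.
#' @param rank taxonomic rank whose confidence is tested.
#' @param min_conf inclusive confidence threshold.
#' @return List with `counts` (retained rows), `removed_taxa`, and
#'   `discarded_fraction` (share of total reads on removed taxa).
#' @export
filter_by_bootstrap <- function(counts, taxonomy, rank = "genus",
                                min_conf = 0.80) {
  check_count_matrix(counts)
  conf_col <- paste0(rank, "_conf")
  if (!conf_col %in% names(taxonomy))
    stopf("unknown rank '%s': taxonomy has no column '%s'", rank, conf_col)
  conf <- taxonomy[[conf_col]][match(rownames(counts), taxonomy$taxon_id)]
  if (anyNA(conf))
    stopf("taxonomy does not cover taxa: %s",
          paste(head(rownames(counts)[is.na(conf)], 5), collapse = ", "))
  if (any(conf < 0 | conf > 1)) stopf("bootstrap confidences must lie in [0, 1]")
  keep <- conf >= min_conf
  list(counts = counts[keep, , drop = FALSE],
       removed_taxa = rownames(counts)[!keep],
       discarded_fraction = sum(counts[!keep, , drop = FALSE]) / sum(counts))
}

#' Keep taxa reaching a minimum relative abundance
#'
#' A taxon is retained iff its proportion reaches `threshold` (inclusive) in
#' at least one sample (`scope = "any_sample"`) or on average across samples
#' (`scope = "mean"`). Remaining rows are NOT renormalized: downstream
#' network inference receives proportions of the original community.
#'
#' @param relab proportion matrix (columns sum to 1).
#' @param threshold inclusive proportion threshold in (0, 1).
#' @param scope where the threshold must be met.
#' @return The filtered proportion matrix.
#' @export
filter_min_relabund <- function(relab, threshold = 0.01,
                                scope = c("any_sample", "mean")) {
  scope <- match.arg(scope)
  if (threshold <= 0 || threshold >= 1) stopf("`threshold` must lie in (0, 1)")
  stat <- if (scope == "any_sample") apply(relab, 1, max) else rowMeans(relab)
  relab[stat >= threshold, , drop = FALSE]
}

#' Aggregate a count table to a taxonomic rank
#'
#' Sums counts of all taxa sharing the same label at `rank`; taxa without a
#' label go to an `"unclassified"` bucket. Per-sample totals are conserved.
#'
#' @param counts taxa x samples matrix.
#' @param taxonomy data.frame with `taxon_id` and a `<rank>` name column.
#' @param rank target rank (default `"genus"`).
#' @return Count matrix with one row per distinct rank label.
#' @export
aggregate_to_rank <- function(counts, taxonomy, rank = "genus") {
  check_count_matrix(counts)
  if (!rank %in% names(taxonomy))
    stopf("unknown rank '%s': taxonomy has no column '%s'", rank, rank)
  lab <- as.character(taxonomy[[rank]][match(rownames(counts), taxonomy$taxon_id)])
  if (any(is.na(match(rownames(counts), taxonomy$taxon_id))))
    stopf("taxonomy does not cover all taxa in `counts`")
  lab[is.na(lab) | lab == ""] <- "unclassified"
  out <- rowsum(counts, group = lab, reorder = TRUE)
  storage.mode(out) <- storage.mode(counts)
  out
}

# Bias-corrected Chao1 richness from one sample's counts:
# S_obs + F1 (F1 - 1) / (2 (F2 + 1)), F1 = singletons, F2 = doubletons.
chao1 <- function(x) {
  f1 <- sum(x == 1); f2 <- sum(x == 2)
  sum(x > 0) + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Per-sample alpha diversity
#'
#' Observed richness, bias-corrected Chao1
#' (`S_obs + F1(F1-1) / (2(F2+1))`, defined even without doubletons),
#' Shannon entropy `H = -sum p_i log p_i` in nats, and Gini-Simpson
#' diversity `D = 1 - sum p_i^2`. Shannon and Simpson are computed with
#' [vegan::diversity()].
#'
#' @param counts taxa x samples matrix; every sample must contain reads.
#' @return data.frame with columns `sample_id`, `observed`, `chao1`,
#'   `shannon`, `simpson`.
#' @export
alpha_diversity <- function(counts) {
  check_count_matrix(counts)
  if (any(colSums(counts) <= 0))
    stopf("empty sample(s): %s",
          paste(colnames(counts)[colSums(counts) <= 0], collapse = ", "))
  tx <- t(counts)
  data.frame(
    sample_id = colnames(counts),
    observed = as.integer(colSums(counts > 0)),
    chao1 = apply(counts, 2, chao1),
    shannon = as.numeric(vegan::diversity(tx, index = "shannon")),
    simpson = as.numeric(vegan::diversity(tx, index = "simpson")),
    row.names = NULL, stringsAsFactors = FALSE)
}
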