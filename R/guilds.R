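#' Read a genus-to-functional-category trait table
#'
#' Expects a tab-separated file with columns `genus`, `category`, `class`
#' (e.g. nutrient-cycling guilds vs. stress-tolerance traits); a genus may
#' appear on several rows.
#'
#' @param path file path.
#' @return data.frame with columns `genus`, `category`, `class`.
#' @export
read_trait_table <- function(path) {
  tr <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  req <- c("genus", "category", "class")
  if (!all(req %in% names(tr)))
    stopf("trait table %s needs columns: %s", path, paste(req, collapse = ", "))
  tr
}

#' Functional-guild abundance profiles
#'
#' The relative abundance of each functional category is the sum of the
#' relative abundances of the genera annotated with it; a genus carrying k
#' categories contributes to all k. Genera absent from the trait table
#' contribute to none and are reported via attributes.
#'
#' @param relab genus x sample proportion matrix.
#' @param traits trait table as from [read_trait_table()].
#' @return category x sample matrix of summed proportions, with attributes
#'   `unmapped_genera` (genera without any category) and
#'   `unmapped_fraction` (their mean summed proportion across samples).
#' @export
guild_abundance <- function(relab, traits) {
  if (is.null(traits) || nrow(traits) == 0) stopf("trait table is empty")
  genera <- rownames(relab)
  cats <- sort(unique(traits$category))
  out <- matrix(0, length(cats), ncol(relab),
                dimnames = list(cats, colnames(relab)))
  for (cat in cats) {
    members <- intersect(unique(traits$genus[traits$category == cat]), genera)
    if (length(members))
      out[cat, ] <- colSums(relab[members, , drop = FALSE])
  }
  unmapped <- setdiff(genera, unique(traits$genus))
  attr(out, "unmapped_genera") <- unmapped
  attr(out, "unmapped_fraction") <-
    if (length(unmapped)) mean(colSums(relab[unmapped, , drop = FALSE])) else 0
  out
}

#' Compare guild abundances across a balanced two-factor design
#'
#' Runs [anova2_raw()] for every functional category against the two
#' metadata factors and adjusts p-values across categories per term with
#' Benjamini-Hochberg.
#'
#' @param guilds category x sample matrix from [guild_abundance()].
#' @param metadata data.frame with `sample_id` plus the factor columns.
#' @param factors two metadata column names (default soil type and season).
#' @param log_transform if `TRUE`, responses are log-transformed (with half
#'   the smallest nonzero value as offset) before the ANOVA.
#' @param alpha significance level applied to the adjusted p-values.
#' @return data.frame with one row per category: F and raw/BH-adjusted p per
#'   term, plus logical significance flags at `alpha`.
#' @export
compare_guilds <- function(guilds, metadata,
                           factors = c("soil_type", "season"),
                           log_transform = FALSE, alpha = 0.05) {
  if (!all(factors %in% names(metadata)))
    stopf("metadata lacks factor column(s): %s",
          paste(setdiff(factors, names(metadata)), collapse = ", "))
  idx <- match(colnames(guilds), metadata$sample_id)
  if (anyNA(idx)) stopf("metadata does not cover all guild-matrix samples")
  f1 <- metadata[[factors[1]]][idx]
  f2 <- metadata[[factors[2]]][idx]
  rows <- lapply(rownames(guilds), function(cat) {
    y <- guilds[cat, ]
    if (log_transform) {
      off <- if (any(y > 0)) min(y[y > 0]) / 2 else 1
      y <- log(y + off)
    }
    if (sd(y) == 0) {
      data.frame(category = cat, F_a = 0, p_a = 1, F_b = 0, p_b = 1,
                 F_ab = 0, p_ab = 1, stringsAsFactors = FALSE)
    } else {
      res <- anova2_raw(y, f1, f2)
      data.frame(category = cat,
                 F_a = res$F[1], p_a = res$p[1],
                 F_b = res$F[2], p_b = res$p[2],
                 F_ab = res$F[3], p_ab = res$p[3], stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  names(out) <- sub("_a$", paste0("_", factors[1]), names(out))
  names(out) <- sub("_b$", paste0("_", factors[2]), names(out))
  names(out) <- sub("_ab$", "_interaction", names(out))
  for (term in c(factors, "interaction")) {
    out[[paste0("padj_", term)]] <- p.adjust(out[[paste0("p_", term)]], "BH")
    out[[paste0("sig_", term)]] <- out[[paste0("padj_", term)]] <= alpha
  }
  out
}
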