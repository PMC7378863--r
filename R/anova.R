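#' Balanced two-way ANOVA from printed cell summaries
#'
#' Reconstructs the classical balanced two-factor ANOVA from per-cell means,
#' standard deviations and a common cell size — the situation when only a
#' published summary table (mean +/- SD per condition) is available. With
#' equal `n` the error mean square is the pooled within-cell variance
#' (mean of the cell variances), and the factor sums of squares follow from
#' the marginal means alone, so the printed F statistics can be reproduced
#' exactly up to rounding of the summaries.
#'
#' @param cells data.frame with one row per cell and columns `a` (factor A
#'   level), `b` (factor B level), `mean`, `sd`, `n`. The design must be
#'   complete and balanced (every A x B combination exactly once, equal
#'   `n >= 2`).
#' @return An `anova2` data.frame with rows for factor A, factor B and the
#'   interaction: columns `term`, `df1`, `df2`, `F`, `p`.
#' @examples
#' cells <- data.frame(a = c("dry", "dry", "rainy", "rainy"),
#'                     b = c("rhizo", "bulk", "rhizo", "bulk"),
#'                     mean = c(10, 11, 20, 21), sd = rep(1, 4), n = 12)
#' anova2_from_summaries(cells)
#' @export
anova2_from_summaries <- function(cells) {
  req <- c("a", "b", "mean", "sd", "n")
  if (!all(req %in% names(cells)))
    stopf("`cells` needs columns: %s", paste(req, collapse = ", "))
  a_lev <- unique(cells$a); b_lev <- unique(cells$b)
  tab <- table(cells$a, cells$b)
  if (any(tab != 1))
    stopf("design must be complete with exactly one summary per cell")
  if (length(unique(cells$n)) != 1)
    stopf("unbalanced design: cell sizes differ (only balanced designs supported)")
  n <- cells$n[1]
  if (n < 2) stopf("cell size must be >= 2")
  if (any(cells$sd < 0)) stopf("cell SDs must be >= 0")
  a <- length(a_lev); b <- length(b_lev)

  M <- matrix(NA_real_, a, b, dimnames = list(a_lev, b_lev))
  M[cbind(match(cells$a, a_lev), match(cells$b, b_lev))] <- cells$mean
  grand <- mean(M)
  mean_a <- rowMeans(M); mean_b <- colMeans(M)
  ss_a <- n * b * sum((mean_a - grand)^2)
  ss_b <- n * a * sum((mean_b - grand)^2)
  inter <- sweep(sweep(M, 1, mean_a), 2, mean_b) + grand
  ss_ab <- n * sum(inter^2)
  mse <- mean(cells$sd^2)            # pooled within-cell variance, equal n
  df_err <- a * b * (n - 1)

  ms <- c(ss_a / (a - 1), ss_b / (b - 1), ss_ab / ((a - 1) * (b - 1)))
  terms <- data.frame(
    term = c("A", "B", "A:B"),
    df1 = c(a - 1, b - 1, (a - 1) * (b - 1)),
    df2 = df_err,
    F = if (mse > 0) ms / mse else ifelse(ms > 0, Inf, 0),
    stringsAsFactors = FALSE)
  terms$p <- pf(terms$F, terms$df1, terms$df2, lower.tail = FALSE)
  class(terms) <- c("anova2", "data.frame")
  terms
}

#' Balanced two-way ANOVA from raw observations
#'
#' Classical fixed-effects two-factor ANOVA with interaction, fitted with
#' [stats::aov()]. Only complete balanced designs are accepted, matching the
#' summary-based routine so the two can be checked against each other.
#'
#' @param values numeric response vector.
#' @param a,b factor labels, one per observation.
#' @return An `anova2` data.frame as in [anova2_from_summaries()].
#' @export
anova2_raw <- function(values, a, b) {
  if (length(values) != length(a) || length(values) != length(b))
    stopf("`values`, `a`, `b` must have equal length")
  a <- factor(a); b <- factor(b)
  tab <- table(a, b)
  if (any(tab == 0)) stopf("missing cell(s) in the design")
  if (length(unique(c(tab))) != 1)
    stopf("unbalanced design: cell sizes differ (only balanced designs supported)")
  if (tab[1] < 2) stopf("cell size must be >= 2")
  if (sd(values) == 0) {             # degenerate: no variance anywhere
    terms <- data.frame(
      term = c("A", "B", "A:B"),
      df1 = c(nlevels(a) - 1, nlevels(b) - 1, (nlevels(a) - 1) * (nlevels(b) - 1)),
      df2 = length(values) - nlevels(a) * nlevels(b),
      F = 0, p = 1, stringsAsFactors = FALSE)
    class(terms) <- c("anova2", "data.frame")
    return(terms)
  }
  fit <- aov(values ~ a * b)
  s <- summary(fit)[[1]]
  df_err <- s[nrow(s), "Df"]
  terms <- data.frame(
    term = c("A", "B", "A:B"),
    df1 = s[1:3, "Df"],
    df2 = df_err,
    F = s[1:3, "F value"],
    p = s[1:3, "Pr(>F)"],
    stringsAsFactors = FALSE)
  rownames(terms) <- NULL
  class(terms) <- c("anova2", "data.frame")
  terms
}

#' @export
print.anova2 <- function(x, ...) {
  cat("Balanced two-way ANOVA\n")
  df <- as.data.frame(x)
  df$F <- signif(df$F, 6); df$p <- signif(df$p, 4)
  print(df, row.names = FALSE)
  invisible(x)
}
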