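# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# stream; seed = NULL leaves the global stream in charge.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Independent per-stage substreams from one master seed.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  as.list(with_seed(seed, sample.int(.Machine$integer.max - 1L, n)))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_count_matrix <- function(counts, what = "counts") {
  if (!is.matrix(counts) || !is.numeric(counts))
    stopf("`%s` must be a numeric matrix (taxa x samples)", what)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("`%s` must carry taxon rownames and sample colnames", what)
  if (anyDuplicated(rownames(counts)))
    stopf("duplicated taxon IDs in `%s`: %s", what,
          paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stopf("duplicated sample IDs in `%s`: %s", what,
          paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (any(counts < 0)) stopf("`%s` contains negative entries", what)
  invisible(counts)
}
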