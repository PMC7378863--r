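# Small in-code fixtures shared across test files.

toy_counts <- function() {
  m <- matrix(c(30L, 10L, 5L, 15L,
                20L, 20L, 10L, 10L,
                50L, 30L, 25L, 15L), nrow = 3, byrow = TRUE,
              dimnames = list(c("OTU_1", "OTU_2", "OTU_3"),
                              c("s1", "s2", "s3", "s4")))
  m
}

toy_taxonomy <- function(otus = c("OTU_1", "OTU_2", "OTU_3"),
                         genera = c("GenA", "GenA", "GenB"),
                         conf = c(0.95, 0.9, 0.99)) {
  data.frame(taxon_id = otus, phylum = "PhyX", phylum_conf = 1,
             genus = genera, genus_conf = conf, stringsAsFactors = FALSE)
}

toy_traits <- function() {
  data.frame(genus = c("GenA", "GenB", "GenB"),
             category = c("N fixation", "N fixation", "denitrification"),
             class = c("nutrient_cycling", "nutrient_cycling",
                       "nutrient_cycling"),
             stringsAsFactors = FALSE)
}

# balanced 2x2 synthetic responses: n per cell, optional cell-mean offsets
balanced_2x2 <- function(n, effects = c(a = 0, b = 0, ab = 0), sd = 1) {
  a <- rep(c("a1", "a2"), each = 2 * n)
  b <- rep(rep(c("b1", "b2"), each = n), 2)
  mu <- effects["a"] * (a == "a2") + effects["b"] * (b == "b2") +
    effects["ab"] * (a == "a2" & b == "b2")
  list(values = rnorm(length(a), mu, sd), a = a, b = b)
}

# small deterministic interaction network from an edge list
edgelist_network <- function(src, dst, sign = rep(1L, length(src))) {
  edges <- data.frame(source = src, target = dst, sign = sign,
                      weight = 1, coefficient = sign * 0.5,
                      stringsAsFactors = FALSE)
  structure(list(nodes = sort(unique(c(src, dst))), edges = edges,
                 self_effects = data.frame(taxon = character(0),
                                           coefficient = numeric(0),
                                           weight = numeric(0)),
                 growth_rates = NULL, taxa = sort(unique(c(src, dst))),
                 config = NULL, subset = NULL,
                 n_samples = NA_integer_, n_orderings = NA_integer_),
            class = "interaction_network")
}

# sign-recovery F1 at the study-scale settings (thin wrapper)
sign_recovery_f1 <- function(seed, noise_sd = 0) {
  sign_recovery_experiment(seed, noise_sd = noise_sd)$f1
}
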