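test_that("count tables round-trip through TSV", {
  path <- withr::local_tempfile(fileext = ".tsv")
  m <- toy_counts()
  write_count_table(m, path)
  expect_identical(read_count_table(path), m)

  st <- simulate_study(n_taxa = 6, seed = 5,
                       design = study_design(n_sites = 1, n_replicates = 2,
                                             depth_range = c(800, 900)))
  write_count_table(st$counts, path)
  expect_identical(read_count_table(path), st$counts)
})

test_that("malformed count tables fail with coordinates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\ts1\ts1", "OTU_1\t1\t2"), path)
  expect_error(read_count_table(path), "duplicated sample column.*s1")

  writeLines(c("taxon_id\ts1\ts2", "OTU_1\t1\t-2", "OTU_2\t0\t1"), path)
  expect_error(read_count_table(path), "row 1.*OTU_1.*s2")

  writeLines(c("taxon_id\ts1", "OTU_1\t1.5"), path)
  expect_error(read_count_table(path), "non-integer")
})

test_that("rarefaction conserves the target depth and is seed-stable", {
  m <- toy_counts()
  r <- rarefy(m, depth = 40, seed = 1)
  expect_true(all(colSums(r) == 40))
  expect_identical(rarefy(m, depth = 40, seed = 1), r)

  # depth equal to the library total returns the library unchanged
  one <- matrix(c(60L, 40L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_identical(rarefy(one, depth = 100, seed = 3), one)

  expect_error(rarefy(m, depth = 70), "s3")
})

test_that("rarefied counts match hypergeometric expectation", {
  # [9000, 1000] subsampled to 1000: E[taxon 1] = 900; band from the exact
  # moments of the mean of 1000 independent hypergeometric draws
  m <- matrix(c(9000L, 1000L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  n_rep <- 1000
  set.seed(99)
  means <- vapply(seq_len(n_rep), function(i) rarefy(m, 1000)[1, 1], 0)
  v <- 1000 * 0.9 * 0.1 * (10000 - 1000) / (10000 - 1)
  half <- 3.29 * sqrt(v / n_rep)
  expect_gt(mean(means), 900 - half)
  expect_lt(mean(means), 900 + half)
})

test_that("relative abundance normalizes columns exactly", {
  m <- matrix(c(3L, 1L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(drop(relative_abundance(m)), c(a = 0.75, b = 0.25))

  ra <- relative_abundance(toy_counts())
  expect_equal(unname(colSums(ra)), rep(1, 4), tolerance = 1e-12)
  expect_equal(relative_abundance(ra), ra, tolerance = 1e-12)  # idempotent

  z <- toy_counts(); z[, 2] <- 0L
  expect_error(relative_abundance(z), "s2")
})

test_that("bootstrap filter is inclusive at the threshold and reports reads", {
  m <- toy_counts()
  tax <- toy_taxonomy(conf = c(1, 1, 1))
  expect_identical(filter_by_bootstrap(m, tax)$counts, m)

  tax2 <- toy_taxonomy(conf = c(0.79, 0.80, 0.81))
  out <- filter_by_bootstrap(m, tax2)
  expect_identical(out$removed_taxa, "OTU_1")
  expect_identical(rownames(out$counts), c("OTU_2", "OTU_3"))

  # discarded taxon holding exactly 5% of reads
  m3 <- matrix(c(5L, 45L, 50L), 3, 1,
               dimnames = list(c("OTU_1", "OTU_2", "OTU_3"), "s1"))
  out3 <- filter_by_bootstrap(m3, tax2)
  expect_equal(out3$discarded_fraction, 0.05)

  expect_error(filter_by_bootstrap(m, tax, rank = "order"), "unknown rank")
})

test_that("minimum relative-abundance filter keeps row maxima >= threshold", {
  relab <- matrix(c(0.009, 0.005, 0.004,
                    0.010, 0.002, 0.001,
                    0.500, 0.600, 0.700,
                    0.300, 0.200, 0.100,
                    0.181, 0.193, 0.195), 5, 3, byrow = TRUE,
                  dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))
  kept <- filter_min_relabund(relab, 0.01)
  expect_setequal(rownames(kept), rownames(relab)[apply(relab, 1, max) >= 0.01])
  expect_false("g1" %in% rownames(kept))   # max 0.009 removed
  expect_true("g2" %in% rownames(kept))    # exactly 0.01 kept (inclusive)
  # no renormalization
  expect_equal(kept["g3", ], relab["g3", ])
  expect_error(filter_min_relabund(relab, 0), "threshold")
})

test_that("rank aggregation conserves totals and matches manual groupby", {
  m <- toy_counts()
  g <- aggregate_to_rank(m, toy_taxonomy())
  expect_equal(colSums(g), colSums(m))
  expect_equal(g["GenA", ], m["OTU_1", ] + m["OTU_2", ])

  otus <- paste0("OTU_", 1:5)
  gen <- c("x", "y", "x", "z", "y")
  m5 <- matrix(1:20, 5, 4, dimnames = list(otus, paste0("s", 1:4)))
  tax5 <- toy_taxonomy(otus = otus, genera = gen, conf = rep(1, 5))
  g5 <- aggregate_to_rank(m5, tax5)
  manual <- rbind(x = m5[1, ] + m5[3, ], y = m5[2, ] + m5[5, ], z = m5[4, ])
  expect_equal(g5[rownames(manual), ], manual)

  tax_na <- tax5; tax_na$genus[4] <- NA
  g_na <- aggregate_to_rank(m5, tax_na)
  expect_true("unclassified" %in% rownames(g_na))
})

test_that("alpha diversity matches closed forms", {
  u <- matrix(rep(5L, 8), 8, 1, dimnames = list(paste0("t", 1:8), "s1"))
  ad <- alpha_diversity(u)
  expect_equal(ad$shannon, log(8), tolerance = 1e-12)
  expect_equal(ad$simpson, 1 - 8 * (1 / 8)^2, tolerance = 1e-12)
  expect_identical(ad$observed, 8L)
  expect_equal(ad$chao1, 8)

  single <- matrix(10L, 1, 1, dimnames = list("t", "s"))
  ad1 <- alpha_diversity(single)
  expect_equal(unlist(ad1[, -1]),
               c(observed = 1, chao1 = 1, shannon = 0, simpson = 0))

  # F1 = 3 singletons, F2 = 1 doubleton: chao1 = 6 + 3*2/(2*2) = 7.5
  v <- matrix(c(5L, 5L, 2L, 1L, 1L, 1L), 6, 1,
              dimnames = list(paste0("t", 1:6), "s1"))
  expect_equal(alpha_diversity(v)$chao1, 7.5)
})

test_that("alpha diversity invariants hold on simulated data", {
  st <- simulate_study(n_taxa = 20, seed = 8,
                       design = study_design(n_sites = 2, n_replicates = 1,
                                             depth_range = c(2000, 3000)))
  ad <- alpha_diversity(st$counts)
  expect_true(all(ad$chao1 >= ad$observed))
  expect_true(all(ad$shannon >= 0))
  expect_true(all(ad$simpson >= 0 & ad$simpson <= 1))

  # merging two identical-composition samples leaves Shannon unchanged
  m <- cbind(a = c(10L, 20L, 30L), b = c(20L, 40L, 60L))
  rownames(m) <- paste0("t", 1:3)
  merged <- matrix(m[, 1] + m[, 2], 3, 1, dimnames = list(rownames(m), "ab"))
  ad2 <- alpha_diversity(cbind(m, merged))
  expect_equal(ad2$shannon[3], ad2$shannon[1], tolerance = 1e-12)

  expect_error(alpha_diversity(matrix(0L, 1, 1, dimnames = list("t", "s"))),
               "empty")
})

test_that("bootstrap filtering commutes with genus aggregation", {
  otus <- paste0("OTU_", 1:6)
  gen <- c("x", "x", "y", "y", "z", "z")
  conf <- c(0.95, 0.95, 0.5, 0.5, 0.99, 0.99)  # whole genera pass or fail
  set.seed(4)
  m <- matrix(rpois(18, 20), 6, 3, dimnames = list(otus, paste0("s", 1:3)))
  storage.mode(m) <- "integer"
  tax <- toy_taxonomy(otus = otus, genera = gen, conf = conf)
  a <- aggregate_to_rank(filter_by_bootstrap(m, tax)$counts, tax)
  g_all <- aggregate_to_rank(m, tax)
  b <- g_all[setdiff(rownames(g_all), "y"), , drop = FALSE]
  expect_equal(a, b)
})
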