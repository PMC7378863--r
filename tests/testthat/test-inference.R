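test_that("design builder produces gLV log-ratios with pseudocount handling", {
  series <- matrix(2, 3, 5, dimnames = list(paste0("t", 1:3), NULL))
  d <- build_design(series)
  expect_true(all(d$response == 0))
  expect_identical(dim(d$response), c(4L, 3L))
  expect_identical(dim(d$design), c(4L, 3L))

  series[2, 3] <- 0                       # zero entry -> finite after pseudocount
  d2 <- build_design(series)
  expect_true(all(is.finite(d2$response)))
  expect_equal(d2$pseudocount, 1)         # half the smallest nonzero value (2)

  expect_error(build_design(series[, 1:2]), "at least 3")
})

test_that("a noiseless Ricker trajectory reproduces its own update rule", {
  p <- sample_glv_parameters(6, connectance = 0.3, seed = 21)
  tr <- simulate_glv(p, runif(6, 0.5, 2), steps = 15)
  d <- build_design(tr$abundances)
  # y_i(t) = r_i + sum_j A[i, j] x_j(t) exactly
  pred <- sweep(d$design %*% t(p$A), 2, p$r, "+")
  expect_equal(unname(d$response), unname(pred), tolerance = 1e-10)
})

test_that("forward selection recovers exact sparse signals", {
  set.seed(22)
  X <- matrix(runif(40 * 6), 40, 6, dimnames = list(NULL, paste0("x", 1:6)))
  y <- 2 * X[, 3]
  fit <- fit_taxon(y, X)
  expect_identical(fit$selected, 3L)
  expect_equal(unname(fit$coefficients[3]), 2, tolerance = 1e-8)
  expect_true(all(fit$coefficients[-3] == 0))

  fit0 <- fit_taxon(rep(0, 40), X)
  expect_length(fit0$selected, 0)
  expect_equal(fit0$intercept, 0)
})

test_that("duplicate predictors break ties toward the lowest column index", {
  set.seed(23)
  x <- runif(30)
  X <- cbind(a = x, b = x, c = runif(30))
  y <- 3 * x
  fit <- fit_taxon(y, X)
  expect_identical(fit$selected, 1L)
})

test_that("constant columns are skipped with a warning", {
  set.seed(24)
  X <- cbind(a = rep(1, 30), b = runif(30))
  y <- 0.5 * X[, "b"] + rnorm(30, 0, 0.01)
  expect_warning(fit <- fit_taxon(y, X), "constant")
  expect_identical(fit$selected, 2L)
})

test_that("consensus inference finds a single planted interaction", {
  # taxon 1 suppresses taxon 2; all other off-diagonals zero
  A <- diag(c(-0.2, -0.2, -0.2))
  A[2, 1] <- -0.25
  p <- list(r = c(0.4, 0.4, 0.4), A = A, noise_sd = 0)
  dimnames(p$A) <- list(paste0("g", 1:3), paste0("g", 1:3))
  tr <- simulate_glv(p, c(2.5, 1, 0.5), steps = 12)
  net <- infer_network(tr$abundances, time_series = TRUE,
                       config = glv_config(n_orderings = 1,
                                           consensus_threshold = 1))
  expect_identical(nrow(net$edges), 1L)
  expect_identical(net$edges$source, "g1")
  expect_identical(net$edges$target, "g2")
  expect_identical(net$edges$sign, -1L)
  expect_equal(net$edges$coefficient, -0.25, tolerance = 1e-6)
})

test_that("constant composition yields an empty consensus network", {
  x <- matrix(0.25, 4, 8, dimnames = list(paste0("g", 1:4), paste0("s", 1:8)))
  net <- suppressWarnings(
    infer_network(x, time_series = TRUE,
                  config = glv_config(n_orderings = 2)))
  expect_identical(nrow(net$edges), 0L)
  expect_length(net$nodes, 0)
})

test_that("raising the consensus threshold never adds edges", {
  st <- simulate_study(n_taxa = 12, seed = 31,
                       design = study_design(n_sites = 3, n_replicates = 2,
                                             depth_range = c(3000, 4000)))
  relab <- relative_abundance(
    aggregate_to_rank(st$counts, st$taxonomy))
  key <- function(net) paste(net$edges$source, net$edges$target, net$edges$sign)
  nets <- lapply(c(0.4, 0.7, 1.0), function(f)
    infer_network(relab, st$metadata, subset = c(soil_type = "rhizosphere"),
                  config = glv_config(n_orderings = 8, consensus_threshold = f),
                  seed = 55))
  expect_true(all(key(nets[[2]]) %in% key(nets[[1]])))
  expect_true(all(key(nets[[3]]) %in% key(nets[[2]])))
  # full consensus at B = 1 equals the single canonical-order fit
  one <- infer_network(relab, st$metadata, subset = c(soil_type = "rhizosphere"),
                       config = glv_config(n_orderings = 1,
                                           consensus_threshold = 1), seed = 1)
  two <- infer_network(relab, st$metadata, subset = c(soil_type = "rhizosphere"),
                       config = glv_config(n_orderings = 1,
                                           consensus_threshold = 1), seed = 2)
  expect_identical(one$edges, two$edges)  # B = 1 is seed-independent
})

test_that("inference is deterministic and equivariant under taxon relabeling", {
  st <- simulate_study(n_taxa = 10, seed = 33,
                       design = study_design(n_sites = 2, n_replicates = 2,
                                             depth_range = c(3000, 4000)))
  relab <- relative_abundance(aggregate_to_rank(st$counts, st$taxonomy))
  cfg <- glv_config(n_orderings = 5)
  n1 <- infer_network(relab, st$metadata, config = cfg, seed = 77)
  n2 <- infer_network(relab, st$metadata, config = cfg, seed = 77)
  expect_identical(n1$edges, n2$edges)

  # permute taxon labels: edges must follow the renaming
  perm <- sample(nrow(relab))
  relab_p <- relab[perm, ]
  map <- setNames(rownames(relab)[perm], rownames(relab)[perm])
  n3 <- infer_network(relab_p, st$metadata, config = cfg, seed = 77)
  e1 <- n1$edges[order(n1$edges$source, n1$edges$target), ]
  e3 <- n3$edges[order(n3$edges$source, n3$edges$target), ]
  expect_equal(e1$source, e3$source)
  expect_equal(e1$target, e3$target)
  expect_equal(e1$sign, e3$sign)
})

test_that("networks round-trip through edge-list TSV and export to GraphML", {
  net <- edgelist_network(c("a", "b", "c"), c("b", "c", "a"),
                          sign = c(1L, -1L, 1L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, path)
  back <- read_network(path)
  expect_identical(back$edges[, c("source", "target", "sign")],
                   net$edges[, c("source", "target", "sign")])
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, gml, format = "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_identical(igraph::ecount(g), 3)
  expect_identical(igraph::vcount(g), 3)
})

test_that("coef() assembles the consensus interaction matrix", {
  net <- edgelist_network(c("a", "b"), c("b", "c"), sign = c(1L, -1L))
  A <- coef(net)
  expect_equal(A["b", "a"], 0.5)
  expect_equal(A["c", "b"], -0.5)
  expect_equal(sum(A != 0), 2)
})

test_that("noiseless sign recovery is strong at study-scale settings", {
  f1 <- vapply(41:43, sign_recovery_f1, 0)
  expect_gte(mean(f1), 0.9)
})
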