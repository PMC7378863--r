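#' Draw ground-truth generalized Lotka-Volterra parameters
#'
#' Samples an interaction matrix and intrinsic growth rates for a community
#' of `n_taxa` taxa. Off-diagonal interactions are placed uniformly at random
#' at `round(connectance * n_taxa * (n_taxa - 1))` positions with random sign
#' and magnitudes uniform on `interaction_scale * c(0.5, 1.5)`. Diagonal
#' entries are negative (self-limitation), so every taxon saturates in
#' isolation. Defaults describe a stable, weakly coupled desert-soil style
#' community: growth rates of 0.2--0.6 per step against self-limitation of
#' 0.15--0.3 put single-taxon equilibria near 1--3 abundance units, and
#' pairwise effects roughly an order of magnitude below self-limitation.
#'
#' @param n_taxa number of taxa (>= 1).
#' @param connectance fraction of the `n_taxa * (n_taxa - 1)` possible
#'   directed interactions that are nonzero, in `[0, 1]`.
#' @param interaction_scale typical magnitude of a nonzero interaction
#'   coefficient (per unit abundance); must be non-negative.
#' @param noise_sd standard deviation of the multiplicative log-normal
#'   process noise applied at each simulation step.
#' @param growth_range,self_limitation uniform ranges for intrinsic growth
#'   rates and for the magnitude of the (negative) diagonal entries.
#' @param seed optional integer seed; the draw is reproducible given the seed
#'   and leaves the caller's RNG stream untouched.
#' @return An object of class `glv_params`: a list with elements `n_taxa`,
#'   `r` (growth-rate vector), `A` (interaction matrix, entry `A[i, j]` is
#'   the per-unit effect of taxon `j` on taxon `i`), `noise_sd`,
#'   `connectance`.
#' @examples
#' p <- sample_glv_parameters(10, connectance = 0.15, seed = 1)
#' sum(p$A[row(p$A) != col(p$A)] != 0)  # 14 interactions
#' @export
sample_glv_parameters <- function(n_taxa, connectance = 0.15,
                                  interaction_scale = 0.08,
                                  noise_sd = 0,
                                  growth_range = c(0.2, 0.6),
                                  self_limitation = c(0.15, 0.3),
                                  seed = NULL) {
  if (n_taxa < 1) stopf("`n_taxa` must be >= 1")
  if (connectance < 0 || connectance > 1)
    stopf("`connectance` must lie in [0, 1]")
  if (interaction_scale < 0) stopf("`interaction_scale` must be >= 0")
  if (noise_sd < 0) stopf("`noise_sd` must be >= 0")
  with_seed(seed, {
    r <- runif(n_taxa, growth_range[1], growth_range[2])
    A <- matrix(0, n_taxa, n_taxa)
    diag(A) <- -runif(n_taxa, self_limitation[1], self_limitation[2])
    n_off <- n_taxa * (n_taxa - 1L)
    k <- round(connectance * n_off)
    if (k > 0) {
      off <- which(row(A) != col(A))
      idx <- sample(off, k)
      A[idx] <- sample(c(-1, 1), k, replace = TRUE) *
        runif(k, 0.5, 1.5) * interaction_scale
    }
    structure(
      list(n_taxa = as.integer(n_taxa), r = r, A = A,
           noise_sd = noise_sd, connectance = connectance),
      class = "glv_params")
  })
}

#' @export
print.glv_params <- function(x, ...) {
  k <- sum(x$A[row(x$A) != col(x$A)] != 0)
  cat(sprintf(
    "gLV parameters: %d taxa, %d interactions (connectance %.3f), noise_sd %.3g\n",
    x$n_taxa, k, x$connectance, x$noise_sd))
  invisible(x)
}

#' Simulate generalized Lotka-Volterra dynamics (Ricker update)
#'
#' Advances the community with the discrete multiplicative (Ricker) map
#' `x_i(t+1) = x_i(t) * exp(r_i + sum_j A[i,j] x_j(t) + eps_i(t))`, with
#' `eps ~ Normal(0, noise_sd^2)` applied on the log scale. The exponential
#' form keeps abundances non-negative by construction; the run is
#' deterministic when `noise_sd = 0`.
#'
#' @param params a [sample_glv_parameters()] object (or a list with `r`,
#'   `A`, `noise_sd`).
#' @param x0 non-negative initial abundance vector, one entry per taxon.
#' @param steps number of update steps `T` (>= 1).
#' @param seed optional integer seed for the process noise.
#' @return An object of class `glv_trajectory`: list with `abundances`
#'   (`n_taxa x (steps + 1)` matrix, column 1 = `x0`) and `times`
#'   (`0:steps`).
#' @examples
#' p <- sample_glv_parameters(3, connectance = 0, seed = 2)
#' tr <- simulate_glv(p, x0 = rep(1, 3), steps = 50)
#' tail(t(tr$abundances), 1)  # near single-taxon equilibria -r/diag(A)
#' @export
simulate_glv <- function(params, x0, steps, seed = NULL) {
  n <- length(params$r)
  if (length(x0) != n) stopf("`x0` must have one entry per taxon (%d)", n)
  if (any(x0 < 0) || any(!is.finite(x0))) stopf("`x0` must be finite and >= 0")
  if (steps < 1) stopf("`steps` must be >= 1")
  noise_sd <- if (is.null(params$noise_sd)) 0 else params$noise_sd
  with_seed(seed, {
    X <- matrix(0, n, steps + 1L)
    X[, 1L] <- x0
    for (t in seq_len(steps)) {
      eps <- if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
      X[, t + 1L] <- X[, t] * exp(params$r + drop(params$A %*% X[, t]) + eps)
      if (any(!is.finite(X[, t + 1L])))
        stopf("trajectory diverged to a non-finite abundance at step %d", t)
    }
    rownames(X) <- if (!is.null(rownames(params$A))) rownames(params$A)
      else paste0("taxon_", seq_len(n))
    structure(list(abundances = X, times = 0:steps), class = "glv_trajectory")
  })
}

#' @export
print.glv_trajectory <- function(x, ...) {
  cat(sprintf("gLV trajectory: %d taxa, %d steps (columns 0..%d)\n",
              nrow(x$abundances), length(x$times) - 1L, length(x$times) - 1L))
  invisible(x)
}

#' Multinomial sequencing model: draw a read-count column
#'
#' Converts one sample's true abundances into a sequencing library by drawing
#' `depth` reads from a multinomial with probabilities proportional to the
#' abundances, so the expected count of taxon `i` is
#' `depth * x_i / sum(x)`.
#'
#' @param abundances non-negative abundance vector with at least one
#'   positive entry.
#' @param depth library size (reads), >= 1.
#' @param seed optional integer seed.
#' @return Integer vector of counts summing exactly to `depth`.
#' @export
sample_reads <- function(abundances, depth, seed = NULL) {
  if (any(abundances < 0)) stopf("`abundances` must be >= 0")
  if (!any(abundances > 0)) stopf("all abundances are zero: nothing to sample")
  if (depth < 1) stopf("`depth` must be >= 1")
  with_seed(seed, {
    counts <- drop(rmultinom(1L, size = as.integer(depth),
                             prob = abundances / sum(abundances)))
    names(counts) <- names(abundances)
    counts
  })
}

#' Describe a balanced soil-survey sampling design
#'
#' The default mirrors a paired rhizosphere/bulk-soil survey with two
#' seasonal campaigns over four sites with three replicate plants per site:
#' 2 x 2 x 4 x 3 = 48 libraries.
#'
#' @param soil_types,seasons factor levels of the two crossed conditions.
#' @param n_sites,n_replicates number of sites and replicates per condition.
#' @param depth_range min/max library size in reads; libraries are drawn
#'   uniformly inside this range (default 50,000--150,000, bracketing typical
#'   16S library sizes around 1e5 reads).
#' @return An object of class `study_design`.
#' @examples
#' d <- study_design()
#' d$n_samples  # 48
#' @export
study_design <- function(soil_types = c("rhizosphere", "bulk"),
                         seasons = c("dry", "rainy"),
                         n_sites = 4, n_replicates = 3,
                         depth_range = c(50000, 150000)) {
  if (n_sites < 1 || n_replicates < 1) stopf("`n_sites` and `n_replicates` must be >= 1")
  if (length(depth_range) != 2 || depth_range[1] > depth_range[2])
    stopf("`depth_range` must be c(min, max) with min <= max")
  structure(
    list(soil_types = soil_types, seasons = seasons,
         n_sites = as.integer(n_sites), n_replicates = as.integer(n_replicates),
         depth_range = as.integer(depth_range),
         n_samples = length(soil_types) * length(seasons) * n_sites * n_replicates),
    class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("study design: %s x %s x %d sites x %d replicates = %d samples, depth %d-%d\n",
              paste(x$soil_types, collapse = "/"), paste(x$seasons, collapse = "/"),
              x$n_sites, x$n_replicates, x$n_samples,
              x$depth_range[1], x$depth_range[2]))
  invisible(x)
}

# Perturb a ground-truth parameter set for one condition: relocate a fraction
# of the interactions (fresh slot, sign and magnitude) and shift growth rates.
perturb_params <- function(params, move_frac, r_shift, interaction_scale) {
  A <- params$A
  off <- which(row(A) != col(A) & A != 0)
  n_move <- round(move_frac * length(off))
  if (n_move > 0 && length(off) > 0) {
    moved <- sample(off, n_move)
    empty <- which(row(A) != col(A) & A == 0)
    dest <- sample(empty, n_move)
    A[moved] <- 0
    A[dest] <- sample(c(-1, 1), n_move, replace = TRUE) *
      runif(n_move, 0.5, 1.5) * interaction_scale
  }
  params$A <- A
  params$r <- pmax(params$r + r_shift, 0.02)
  params
}

#' Generate a full synthetic community study
#'
#' Builds a ground-truth gLV community, derives condition-specific parameter
#' sets (soil type relocates a fraction of the interactions; the rainy season
#' boosts growth rates and relocates a smaller fraction), simulates noisy
#' abundance trajectories per soil type with the dry season preceding the
#' rainy one, splits each genus into 1--3 OTUs, and draws multinomial
#' sequencing libraries at depths uniform in the design's `depth_range`.
#' Successive samples within a soil type are successive states of that
#' soil's trajectory (`sample_every` steps apart), so a (season, site,
#' replicate) ordering of the samples is a genuine time course.
#'
#' @param design a [study_design()].
#' @param n_taxa number of genera in the ground-truth community.
#' @param connectance,interaction_scale,noise_sd passed to
#'   [sample_glv_parameters()].
#' @param effect_size condition-effect magnitude: the fraction of
#'   interactions relocated between soil types (`0.4 * effect_size` between
#'   seasons) and the scale of the seasonal growth-rate shift.
#' @param sample_every trajectory steps between consecutive samples.
#' @param burn_in steps discarded before the first sample.
#' @param otus_per_genus integer range: each genus is observed as this many
#'   OTUs, its abundance split by fixed random weights.
#' @param seed master seed; all stages draw from substreams derived from it.
#' @return An object of class `community_study`: list with `counts` (OTU x
#'   sample integer matrix), `metadata` (data.frame: `sample_id`,
#'   `soil_type`, `season`, `site`, `replicate`), `taxonomy` (data.frame:
#'   `taxon_id`, `phylum`, `phylum_conf`, `genus`, `genus_conf`), `traits`
#'   (data.frame: `genus`, `category`, `class`), `truth` (named list of the
#'   four condition interaction matrices), `params`, `design`.
#' @examples
#' st <- simulate_study(n_taxa = 12, seed = 1,
#'                      design = study_design(n_sites = 2, n_replicates = 1,
#'                                            depth_range = c(2000, 4000)))
#' dim(st$counts); table(st$metadata$soil_type, st$metadata$season)
#' @export
simulate_study <- function(design = study_design(), n_taxa = 40,
                           connectance = 0.15, interaction_scale = 0.04,
                           noise_sd = 0.05, effect_size = 0.5,
                           sample_every = 2, burn_in = 10,
                           otus_per_genus = c(1, 3), seed = NULL) {
  if (design$depth_range[1] > design$depth_range[2])
    stopf("depth_range min exceeds max")
  seeds <- derive_seeds(seed, 4L)
  genera <- sprintf("Genus_%03d", seq_len(n_taxa))

  phyla <- c("Actinobacteria", "Proteobacteria", "Acidobacteria",
             "Chloroflexi", "Firmicutes", "Bacteroidetes", "Gemmatimonadetes")
  guilds <- list(
    nutrient_cycling = c("N fixation", "denitrification",
                         "P solubilization", "nitrification"),
    stress_tolerance = c("spore formation", "desiccation tolerance",
                         "salt tolerance", "thermotolerance"),
    environmental_adaptation = c("EPS production", "antibiotic production",
                                 "filamentous growth", "nutrient storage"))

  with_seed(seeds[[2]], {
    # genus -> OTU split weights (independent of the dynamics)
    n_otus <- sample(otus_per_genus[1]:otus_per_genus[2], n_taxa, replace = TRUE)
    otu_genus <- rep(genera, n_otus)
    otu_ids <- sprintf("OTU_%04d", seq_along(otu_genus))
    split_w <- lapply(n_otus, function(k) { w <- runif(k, 0.2, 1); w / sum(w) })
    # taxonomy with bootstrap confidences; ~10% of OTUs weakly classified
    genus_phylum <- sample(phyla, n_taxa, replace = TRUE)
    weak <- runif(length(otu_ids)) < 0.1
    taxonomy <- data.frame(
      taxon_id = otu_ids,
      phylum = genus_phylum[match(otu_genus, genera)],
      phylum_conf = round(runif(length(otu_ids), 0.9, 1), 2),
      genus = otu_genus,
      genus_conf = round(ifelse(weak, runif(length(otu_ids), 0.5, 0.79),
                                runif(length(otu_ids), 0.85, 1)), 2),
      stringsAsFactors = FALSE)
    # traits: each genus carries 0-3 functional categories
    traits <- do.call(rbind, lapply(genera, function(g) {
      k <- sample(0:3, 1, prob = c(0.15, 0.4, 0.3, 0.15))
      if (k == 0) return(NULL)
      cls <- sample(names(guilds), k, replace = FALSE)
      data.frame(genus = g, category = vapply(guilds[cls], sample, "", size = 1),
                 class = cls, row.names = NULL, stringsAsFactors = FALSE)
    }))
  })

  # Condition-specific ground truths (soil effect > season effect) and
  # per-soil trajectories: burn-in, then dry block, then rainy block. A
  # surveyed community is persistent by construction, so draws whose
  # trajectories diverge are re-run from fresh initial states and, failing
  # that, from a fresh base parameter draw.
  n_block <- design$n_sites * design$n_replicates
  make_cond_params <- function(base) with_seed(seeds[[2]] + 1L, {
    cond_params <- list()
    for (soil in design$soil_types) {
      p_soil <- if (soil == design$soil_types[1]) base
        else perturb_params(base, effect_size, 0, interaction_scale)
      for (season in design$seasons) {
        p <- if (season == design$seasons[1]) p_soil
          else perturb_params(p_soil, 0.4 * effect_size,
                              runif(n_taxa, 0, 0.2 * effect_size),
                              interaction_scale)
        cond_params[[paste(soil, season, sep = "_")]] <- p
      }
    }
    cond_params
  })
  make_states <- function(cond_params) {
    states <- list()
    for (soil in design$soil_types) {
      x <- runif(n_taxa, 0.3, 3)
      p_dry <- cond_params[[paste(soil, design$seasons[1], sep = "_")]]
      x <- simulate_glv(p_dry, x, burn_in)$abundances[, burn_in + 1L]
      for (season in design$seasons) {
        p <- cond_params[[paste(soil, season, sep = "_")]]
        for (k in seq_len(n_block)) {
          x <- simulate_glv(p, x, sample_every)$abundances[, sample_every + 1L]
          states[[paste(soil, season, k, sep = "_")]] <- x
        }
      }
    }
    states
  }
  states <- NULL
  for (redraw in 0:9) {
    base <- sample_glv_parameters(n_taxa, connectance, interaction_scale,
                                  noise_sd = noise_sd,
                                  seed = seeds[[1]] + 7919L * redraw)
    dimnames(base$A) <- list(genera, genera)
    cond_params <- make_cond_params(base)
    for (attempt in seq_len(5)) {
      states <- with_seed(seeds[[3]] + attempt - 1L,
                          tryCatch(make_states(cond_params),
                                   error = function(e) NULL))
      if (!is.null(states)) break
    }
    if (!is.null(states)) break
  }
  if (is.null(states))
    stopf("community dynamics diverged for every parameter draw; lower `interaction_scale` or `effect_size`")

  # metadata in canonical (soil, season, site, replicate) order
  metadata <- expand.grid(replicate = seq_len(design$n_replicates),
                          site = seq_len(design$n_sites),
                          season = design$seasons,
                          soil_type = design$soil_types,
                          stringsAsFactors = FALSE)
  metadata <- metadata[, c("soil_type", "season", "site", "replicate")]
  metadata$sample_id <- sprintf("S%02d_%s_%s_site%d_r%d", seq_len(nrow(metadata)),
                                substr(metadata$soil_type, 1, 4), metadata$season,
                                metadata$site, metadata$replicate)
  metadata <- metadata[, c("sample_id", "soil_type", "season", "site", "replicate")]

  counts <- matrix(0L, length(otu_ids), nrow(metadata),
                   dimnames = list(otu_ids, metadata$sample_id))
  with_seed(seeds[[4]], {
    depths <- sample(design$depth_range[1]:design$depth_range[2],
                     nrow(metadata), replace = TRUE)
    for (s in seq_len(nrow(metadata))) {
      soil <- metadata$soil_type[s]; season <- metadata$season[s]
      k <- (metadata$site[s] - 1L) * design$n_replicates + metadata$replicate[s]
      gx <- states[[paste(soil, season, k, sep = "_")]]
      ox <- unlist(lapply(seq_along(genera), function(g) gx[g] * split_w[[g]]))
      counts[, s] <- sample_reads(ox, depths[s])
    }
  })

  structure(
    list(counts = counts, metadata = metadata, taxonomy = taxonomy,
         traits = traits,
         truth = lapply(cond_params, `[[`, "A"),
         params = base, design = design),
    class = "community_study")
}

#' @export
print.community_study <- function(x, ...) {
  cat(sprintf("synthetic community study: %d OTUs (%d genera) x %d samples\n",
              nrow(x$counts), x$params$n_taxa, ncol(x$counts)))
  print(x$design)
  invisible(x)
}

#' Write a simulated study to tab-separated files
#'
#' Emits `counts.tsv`, `metadata.tsv`, `taxonomy.tsv`, `traits.tsv` and one
#' `truth_A_<condition>.tsv` per condition into `dir` (UTF-8, header row,
#' IDs in column 1).
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  w <- function(df, name, rows = FALSE) {
    path <- file.path(dir, name)
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = rows, col.names = TRUE)
    files <<- c(files, path)
  }
  write_count_table(study$counts, file.path(dir, "counts.tsv"))
  files <- c(files, file.path(dir, "counts.tsv"))
  w(study$metadata, "metadata.tsv")
  w(study$taxonomy, "taxonomy.tsv")
  w(study$traits, "traits.tsv")
  for (cond in names(study$truth)) {
    A <- study$truth[[cond]]
    df <- data.frame(taxon_id = rownames(A), A, check.names = FALSE)
    w(df, sprintf("truth_A_%s.tsv", cond))
  }
  invisible(files)
}
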