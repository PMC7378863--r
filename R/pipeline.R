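#' Configuration for a full pipeline run
#'
#' Collects every knob of the simulate -> process -> guilds -> infer ->
#' analyze -> null chain. Inputs are either simulated (`simulate = list()`
#' arguments for [simulate_study()]) or read from tab-separated files
#' (`counts_path` etc. as written by [write_study()]).
#'
#' @param out_dir output directory for all artifacts.
#' @param seed master seed; every stage draws from substreams derived from
#'   it.
#' @param simulate named list of [simulate_study()] arguments (ignored when
#'   `counts_path` is given).
#' @param counts_path,metadata_path,taxonomy_path,traits_path optional input
#'   files replacing simulation.
#' @param min_bootstrap,min_relabund,rarefy_depth processing thresholds;
#'   `rarefy_depth = "auto"` uses the smallest library.
#' @param inference a [glv_config()].
#' @param null_n null-ensemble size per network.
#' @param alpha significance level for null comparison and guild tests.
#' @return An object of class `pipeline_config` (a plain list; it
#'   round-trips through serialization unchanged).
#' @export
pipeline_config <- function(out_dir, seed = 1, simulate = list(),
                            counts_path = NULL, metadata_path = NULL,
                            taxonomy_path = NULL, traits_path = NULL,
                            min_bootstrap = 0.8, min_relabund = 0.01,
                            rarefy_depth = "auto",
                            inference = glv_config(),
                            null_n = 100, alpha = 0.05) {
  structure(list(out_dir = out_dir, seed = seed, simulate = simulate,
                 counts_path = counts_path, metadata_path = metadata_path,
                 taxonomy_path = taxonomy_path, traits_path = traits_path,
                 min_bootstrap = min_bootstrap, min_relabund = min_relabund,
                 rarefy_depth = rarefy_depth, inference = inference,
                 null_n = null_n, alpha = alpha),
            class = "pipeline_config")
}

# The eight condition networks: soil-type scheme x season, as reported in
# the study design (bulk soil is not pooled across seasons).
pipeline_subsets <- function() {
  list(both_dry = c(season = "dry"),
       both_rainy = c(season = "rainy"),
       both_all_seasons = NULL,
       rhizosphere_dry = c(soil_type = "rhizosphere", season = "dry"),
       rhizosphere_rainy = c(soil_type = "rhizosphere", season = "rainy"),
       rhizosphere_all_seasons = c(soil_type = "rhizosphere"),
       bulk_dry = c(soil_type = "bulk", season = "dry"),
       bulk_rainy = c(soil_type = "bulk", season = "rainy"))
}

stage_log <- function(stage, ...) {
  message(sprintf("[agavenet] %s: %s", stage, sprintf(...)))
}

#' Run the full analysis pipeline
#'
#' Orchestrates one reproducible end-to-end run: obtain counts (simulated
#' or read from disk), rarefy and compute alpha diversity, filter by
#' taxonomy bootstrap, aggregate to genus, apply the minimum
#' relative-abundance filter, build guild profiles with their two-way
#' ANOVA, infer the eight condition networks, and attach a property
#' report, hub table and null-model summary to each. All artifacts are
#' written under `out_dir` (`counts/`, `networks/`, `reports/`, `null/`)
#' plus one consolidated `report.json`; the run is deterministic given the
#' master seed.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, an object of class `run_report`: list with
#'   `network_table` (per-network global measures), `hub_table`,
#'   `alpha_anova`, `guild_anova`, `null_summaries`, `paths`, `config`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) stopf("`config` must be a pipeline_config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("counts", "networks", "reports", "null"))
    dir.create(file.path(config$out_dir, d), showWarnings = FALSE)
  seeds <- derive_seeds(config$seed, 4L)

  # --- inputs -------------------------------------------------------------
  t0 <- proc.time()[3]
  if (is.null(config$counts_path)) {
    study <- do.call(simulate_study, c(config$simulate, list(seed = seeds[[1]])))
    counts <- study$counts; metadata <- study$metadata
    taxonomy <- study$taxonomy; traits <- study$traits
    write_study(study, file.path(config$out_dir, "counts"))
  } else {
    counts <- read_count_table(config$counts_path)
    metadata <- read.delim(config$metadata_path, stringsAsFactors = FALSE)
    taxonomy <- read.delim(config$taxonomy_path, stringsAsFactors = FALSE)
    traits <- read_trait_table(config$traits_path)
  }
  stage_log("input", "%d taxa x %d samples (%.1fs)",
            nrow(counts), ncol(counts), proc.time()[3] - t0)

  # --- processing ---------------------------------------------------------
  t0 <- proc.time()[3]
  depth <- if (identical(config$rarefy_depth, "auto"))
    min(colSums(counts)) else config$rarefy_depth
  rare <- rarefy(counts, depth, seed = seeds[[2]])
  alpha_div <- alpha_diversity(rare)
  boot <- filter_by_bootstrap(rare, taxonomy, rank = "genus",
                              min_conf = config$min_bootstrap)
  genus_counts <- aggregate_to_rank(boot$counts, taxonomy, rank = "genus")
  genus_relab <- relative_abundance(genus_counts)
  genus_relab <- filter_min_relabund(genus_relab,
                                     threshold = config$min_relabund)
  write_count_table(genus_counts, file.path(config$out_dir, "counts",
                                            "genus_counts.tsv"))
  write.table(alpha_div, file.path(config$out_dir, "reports",
                                   "alpha_diversity.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  stage_log("process", "rarefied to %d; %d genera pass filters (%.1fs)",
            depth, nrow(genus_relab), proc.time()[3] - t0)

  idx <- match(alpha_div$sample_id, metadata$sample_id)
  alpha_anova <- anova2_raw(alpha_div$shannon,
                            metadata$soil_type[idx], metadata$season[idx])

  # --- guilds -------------------------------------------------------------
  t0 <- proc.time()[3]
  guilds <- guild_abundance(genus_relab, traits)
  guild_anova <- compare_guilds(guilds, metadata, alpha = config$alpha)
  write.table(guild_anova, file.path(config$out_dir, "reports", "guild_anova.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  stage_log("guilds", "%d categories compared (%.1fs)",
            nrow(guild_anova), proc.time()[3] - t0)

  # --- networks -----------------------------------------------------------
  subsets <- pipeline_subsets()
  net_seeds <- derive_seeds(seeds[[3]], length(subsets))
  null_seeds <- derive_seeds(seeds[[4]], length(subsets))
  networks <- list(); reports <- list(); hubs <- list(); nulls <- list()
  for (k in seq_along(subsets)) {
    nm <- names(subsets)[k]
    t0 <- proc.time()[3]
    net <- infer_network(genus_relab, metadata, subset = subsets[[k]],
                         config = config$inference, seed = net_seeds[[k]])
    write_network(net, file.path(config$out_dir, "networks",
                                 paste0("net_", nm, ".tsv")))
    write_network(net, file.path(config$out_dir, "networks",
                                 paste0("net_", nm, ".graphml")),
                  format = "graphml")
    if (length(net$nodes) > 0) {
      rep_k <- network_metrics(net)
      hub_k <- identify_hubs(net)
      null_k <- null_model_test(net, n = config$null_n,
                                alpha = config$alpha, seed = null_seeds[[k]])
      write.table(as.data.frame(null_k),
                  file.path(config$out_dir, "null", paste0("null_", nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      memb <- rep_k$communities
      write.table(data.frame(node = names(memb), module = memb),
                  file.path(config$out_dir, "reports", paste0("modules_", nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      rep_k <- NULL; hub_k <- NULL; null_k <- NULL
    }
    networks[[nm]] <- net
    reports[nm] <- list(rep_k)     # keep NULL entries for empty networks
    hubs[nm] <- list(hub_k)
    nulls[nm] <- list(null_k)
    stage_log("infer", "%s: %d nodes, %d edges (%.1fs)", nm,
              length(net$nodes), nrow(net$edges), proc.time()[3] - t0)
  }

  network_table <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    if (is.null(r)) return(data.frame(network = nm, order = 0, size = 0,
                                      density = NA, mean_degree = NA,
                                      clustering = NA, modularity = NA,
                                      n_modules = NA))
    data.frame(network = nm, order = r$order, size = r$size,
               density = r$density, mean_degree = r$mean_degree,
               clustering = r$clustering, modularity = r$modularity,
               n_modules = r$n_modules)
  }))
  hub_table <- do.call(rbind, lapply(names(hubs), function(nm) {
    h <- hubs[[nm]]
    if (is.null(h)) return(NULL)
    data.frame(network = nm,
               hubs_total = paste(h$hubs_total, collapse = ","),
               max_total = h$max_total,
               hubs_in = paste(h$hubs_in, collapse = ","),
               max_in = h$max_in,
               hubs_out = paste(h$hubs_out, collapse = ","),
               max_out = h$max_out, stringsAsFactors = FALSE)
  }))

  # --- consolidated report ------------------------------------------------
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA, null = "null", force = TRUE)
  cfg_file <- file.path(config$out_dir, "config.json")
  writeLines(cfg_json, cfg_file)
  report <- list(
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = config$seed,
    network_table = network_table,
    hub_table = hub_table,
    alpha_anova = as.data.frame(alpha_anova),
    guild_anova = guild_anova,
    null_summaries = lapply(nulls, function(x)
      if (is.null(x)) NULL else as.data.frame(x)))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       null = "null")
  out <- structure(
    list(network_table = network_table, hub_table = hub_table,
         alpha_anova = alpha_anova, guild_anova = guild_anova,
         null_summaries = nulls, networks = networks, reports = reports,
         hubs = hubs, alpha_diversity = alpha_div,
         paths = list(out_dir = config$out_dir,
                      report = file.path(config$out_dir, "report.json")),
         config = config),
    class = "run_report")
  stage_log("done", "report at %s", out$paths$report)
  invisible(out)
}

#' @export
print.run_report <- function(x, ...) {
  cat("pipeline run report\n")
  df <- x$network_table
  df[] <- lapply(df, function(v) if (is.numeric(v)) signif(v, 4) else v)
  print(df, row.names = FALSE)
  invisible(x)
}
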