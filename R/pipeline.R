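# End-to-end orchestration: simulate-or-load -> rarefy -> alpha/beta ->
# guilds -> core -> per-plant-type networks -> comparison, under one master
# seed, writing every stage's output plus a machine-readable manifest.

#' Pipeline configuration
#'
#' Exactly one of `input_paths` (named paths: `counts`, `metadata`,
#' `taxonomy`, `guild_db`) or `sim` (a [sim_config()]) must be given.
#'
#' @param input_paths Named list/vector of input file paths, or `NULL`.
#' @param sim A [sim_config()], or `NULL`.
#' @param depth Rarefaction depth (default 25556).
#' @param permutations Permutations for PERMANOVA/dispersion/envfit
#'   (default 999).
#' @param prevalence Core prevalence threshold (default 0.75).
#' @param r_threshold Network correlation threshold (default 0.6).
#' @param alpha_network Network FDR threshold (default 0.01).
#' @param top_fraction Hub fraction (default 0.02).
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_paths = NULL, sim = NULL, depth = 25556,
                            permutations = 999, prevalence = 0.75,
                            r_threshold = 0.6, alpha_network = 0.01,
                            top_fraction = 0.02, seed = 1, out_dir = "milletmyco_out") {
  .assert(xor(is.null(input_paths), is.null(sim)),
          "exactly one of input_paths and sim must be given")
  if (!is.null(input_paths)) {
    input_paths <- as.list(input_paths)
    .assert(all(c("counts", "metadata", "taxonomy", "guild_db") %in% names(input_paths)),
            "input_paths needs counts, metadata, taxonomy and guild_db")
  }
  .assert(depth >= 1, "depth must be >= 1")
  .assert(permutations >= 1, "permutations must be >= 1")
  .assert(prevalence > 0 && prevalence <= 1, "prevalence must lie in (0, 1]")
  .assert(r_threshold >= 0 && r_threshold < 1, "r_threshold must lie in [0, 1)")
  .assert(alpha_network > 0 && alpha_network <= 1, "alpha_network must lie in (0, 1]")
  .assert(top_fraction > 0 && top_fraction <= 1, "top_fraction must lie in (0, 1]")
  structure(list(input_paths = input_paths, sim = sim, depth = depth,
                 permutations = permutations, prevalence = prevalence,
                 r_threshold = r_threshold, alpha_network = alpha_network,
                 top_fraction = top_fraction, seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes every stage with child seeds derived from the master seed,
#' writes each output under `config$out_dir`, and records a manifest
#' (parameters, child seeds, output files with MD5 hashes, dropped
#' samples/OTUs with reasons) as `manifest.json`. Re-running with an
#' identical configuration reproduces identical files; with
#' `resume = TRUE`, stages whose outputs already exist are not recomputed.
#'
#' @param config A [pipeline_config()].
#' @param resume Skip stages whose outputs already exist (default FALSE).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, resume = FALSE) {
  .assert(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out, "manifest.json")
  if (resume && file.exists(manifest_path)) {
    prev <- jsonlite::read_json(manifest_path)
    files <- unlist(lapply(prev$stages, function(s) unlist(s$files)))
    if (length(files) && all(file.exists(files))) {
      message("run_pipeline: all outputs present, resuming from manifest")
      return(invisible(prev))
    }
  }
  seed <- config$seed
  params <- unclass(config)
  manifest <- list(parameters = params[setdiff(names(params), c("sim", "input_paths"))],
                   child_seeds = list(), stages = list(), log = character(0))
  log_note <- function(...) {
    manifest$log <<- c(manifest$log, sprintf(...))
    message(sprintf(...))
  }
  record <- function(stage, files) {
    manifest$stages[[stage]] <<- list(
      files = as.list(files),
      md5 = as.list(unname(tools::md5sum(unlist(files)))))
  }

  # 1. inputs: simulate or load
  in_dir <- file.path(out, "inputs")
  if (!is.null(config$sim)) {
    manifest$child_seeds$simulate <- config$sim$seed
    ds <- generate_dataset(config$sim)
    paths <- write_dataset(ds, in_dir)
    counts <- ds$counts; metadata <- ds$metadata
    taxonomy <- ds$taxonomy; guild_db <- ds$guild_db
    record("inputs", paths)
  } else {
    counts <- read_count_table(config$input_paths$counts)
    metadata <- read_metadata(config$input_paths$metadata)
    taxonomy <- read_taxonomy(config$input_paths$taxonomy)
    guild_db <- read_guild_db(config$input_paths$guild_db)
    record("inputs", config$input_paths)
  }
  validate_dataset(counts, metadata, taxonomy, strict = FALSE)

  # 2. rarefaction
  manifest$child_seeds$rarefy <- child_seed(seed, "rarefy")
  dropped <- colnames(counts)[colSums(counts) < config$depth]
  if (length(dropped)) {
    log_note("rarefy: dropped %d sample(s) below depth %d [reason=low_depth]: %s",
             length(dropped), config$depth, paste(dropped, collapse = ", "))
  }
  rare <- suppressWarnings(
    rarefy_counts(counts, config$depth, seed = manifest$child_seeds$rarefy))
  f_rare <- write_count_table(rare, file.path(out, "rarefied.tsv"))
  record("rarefy", c(rarefied = f_rare))

  # 3. alpha diversity
  alpha <- alpha_table(rare, metadata)
  record("alpha", c(alpha = .write_tsv(alpha, file.path(out, "alpha.tsv"))))

  # 4. beta diversity: distances, NMDS, PERMANOVA, dispersion, envfit
  d <- bray_curtis(rare)
  meta_r <- metadata[match(colnames(rare), metadata$sample_id), , drop = FALSE]
  manifest$child_seeds$nmds <- child_seed(seed, "nmds")
  ord <- nmds(d, k = 2, seed = manifest$child_seeds$nmds)
  manifest$child_seeds$permanova <- child_seed(seed, "permanova")
  pmv <- permanova(d, meta_r, permutations = config$permutations,
                   seed = manifest$child_seeds$permanova)
  manifest$child_seeds$dispersion <- child_seed(seed, "dispersion")
  disp <- group_dispersion(d, meta_r$plant_type, n_perm = config$permutations,
                           seed = manifest$child_seeds$dispersion)
  manifest$child_seeds$envfit <- child_seed(seed, "envfit")
  env <- fit_env_vectors(ord, meta_r, n_perm = config$permutations,
                         seed = manifest$child_seeds$envfit)
  beta_files <- c(
    distances = .write_tsv(
      data.frame(sample_id = colnames(rare), as.matrix(d), check.names = FALSE),
      file.path(out, "bray_curtis.tsv")),
    scores = .write_tsv(
      data.frame(sample_id = rownames(ord$points), ord$points,
                 stress = ord$stress, check.names = FALSE),
      file.path(out, "nmds_scores.tsv")),
    permanova = .write_tsv(as.data.frame(pmv), file.path(out, "permanova.tsv")),
    dispersion = .write_tsv(
      data.frame(sample_id = names(disp$distances),
                 distance_to_centroid = disp$distances,
                 group = disp$groups, F = disp$F, p = disp$p),
      file.path(out, "dispersion.tsv")),
    envfit = .write_tsv(env, file.path(out, "envfit.tsv")))
  record("beta", beta_files)

  # 5. guilds
  ann <- assign_guilds(taxonomy, guild_db)
  abund <- group_relative_abundance(rare, ann)
  soil_corr <- soil_trophic_correlation(abund, meta_r)
  guild_files <- c(
    annotations = .write_tsv(ann, file.path(out, "guild_annotations.tsv")),
    trophic_abundance = .write_tsv(
      data.frame(sample_id = rownames(abund), abund, check.names = FALSE),
      file.path(out, "trophic_abundance.tsv")),
    soil_correlation = .write_tsv(soil_corr, file.path(out, "soil_trophic_correlation.tsv")))
  record("guilds", guild_files)

  # 6. core mycobiome (all samples pooled)
  core <- core_mycobiome(rare, config$prevalence)
  core_df <- data.frame(otu_id = core$otu_ids, prevalence = core$prevalence,
                        always_present = core$otu_ids %in% core$always_present_ids)
  core_files <- c(
    core = .write_tsv(core_df, file.path(out, "core_otus.tsv")),
    summary = .write_tsv(summary(core), file.path(out, "core_summary.tsv")))
  record("core", core_files)

  # 7. per-plant-type co-occurrence networks
  nets <- list(); metrics <- list(); hubs <- list()
  net_files <- c()
  for (pt in c("cultivated", "wild")) {
    samples <- meta_r$sample_id[meta_r$plant_type == pt]
    stratum <- rare[core$otu_ids, intersect(colnames(rare), samples), drop = FALSE]
    net <- withCallingHandlers(
      build_network(stratum, r_threshold = config$r_threshold,
                    alpha = config$alpha_network, annotations = ann, label = pt),
      warning = function(w) {
        log_note("network[%s]: %s [reason=constant_otu]", pt, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    nets[[pt]] <- net
    if (nrow(net$nodes) > 0) {
      nm <- node_metrics(net)
      nwm <- network_metrics(net, seed = child_seed(seed, paste0("louvain_", pt)))
      hubs[[pt]] <- identify_hubs(nm, config$top_fraction)
    } else {
      log_note("network[%s]: no edges survive the thresholds [reason=empty_network]", pt)
      nm <- data.frame(otu_id = character(0), degree = numeric(0),
                       betweenness = numeric(0), closeness = numeric(0),
                       eigenvector = numeric(0))
      nwm <- data.frame(n_nodes = 0, n_edges = 0)
      hubs[[pt]] <- list(hubs = character(0), degree_cutoff = NA, betweenness_cutoff = NA)
    }
    metrics[[pt]] <- nm
    pre <- file.path(out, paste0("network_", pt))
    net_files <- c(net_files, stats::setNames(c(
      write_network(net, paste0(pre, ".graphml"), "graphml"),
      write_network(net, paste0(pre, "_edges.csv"), "edge_csv"),
      .write_tsv(nm, paste0(pre, "_node_metrics.tsv")),
      .write_tsv(nwm, paste0(pre, "_metrics.tsv")),
      .write_tsv({
        hub_ids <- hubs[[pt]]$hubs
        data.frame(otu_id = hub_ids,
                   guild = ann$guild[match(hub_ids, ann$otu_id)],
                   degree_cutoff = rep(hubs[[pt]]$degree_cutoff, length(hub_ids)),
                   betweenness_cutoff = rep(hubs[[pt]]$betweenness_cutoff,
                                            length(hub_ids)))
      }, paste0(pre, "_hubs.tsv"))),
      paste0(pt, c("_graphml", "_edges", "_node_metrics", "_metrics", "_hubs"))))
  }
  record("networks", net_files)

  # 8. comparison
  comp <- if (nrow(metrics$cultivated) > 0 && nrow(metrics$wild) > 0) {
    compare_networks(metrics$cultivated, metrics$wild,
                     labels = c("cultivated", "wild"))
  } else {
    log_note("comparison skipped: at least one network is empty [reason=empty_network]")
    data.frame(metric = character(0), median_cultivated = numeric(0),
               median_wild = numeric(0), W = numeric(0), p = numeric(0))
  }
  shared <- intersect(hubs$cultivated$hubs, hubs$wild$hubs)
  comp_files <- c(
    wilcoxon = .write_tsv(comp, file.path(out, "network_comparison.tsv")),
    shared_hubs = .write_tsv(data.frame(otu_id = shared),
                             file.path(out, "shared_hubs.tsv")))
  record("comparison", comp_files)

  manifest$n_samples <- ncol(rare)
  manifest$n_otus <- nrow(rare)
  jsonlite::write_json(manifest, manifest_path,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
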