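# Synthetic OTU-table generator with planted ground truth.
#
# Counts follow a Gaussian copula with negative-binomial marginals: a
# multivariate normal draw per sample is probability-transformed and pushed
# through per-OTU negative-binomial quantile functions, then multinomially
# subsampled to the sample's library size. The copula preserves rank
# correlation approximately, matching the Spearman-based network analysis
# downstream. Planted structure (correlation blocks, hub-and-spoke factors,
# site/plant effects, soil-guild correlations) is reported as ground truth
# for parameter-recovery tests.

DEFAULT_SITES <- c("Darou-Mousty", "Dya", "Nioro")

# plausible lineages for the genera in the miniature guild lookup
.GENUS_LINEAGE <- local({
  tab <- rbind(
    c("Curvularia",      "Pleosporaceae",     "Pleosporales",    "Dothideomycetes",  "Ascomycota"),
    c("Bipolaris",       "Pleosporaceae",     "Pleosporales",    "Dothideomycetes",  "Ascomycota"),
    c("Cochliobolus",    "Pleosporaceae",     "Pleosporales",    "Dothideomycetes",  "Ascomycota"),
    c("Exserohilum",     "Pleosporaceae",     "Pleosporales",    "Dothideomycetes",  "Ascomycota"),
    c("Helminthosporium","Massarinaceae",     "Pleosporales",    "Dothideomycetes",  "Ascomycota"),
    c("Magnaporthe",     "Magnaporthaceae",   "Magnaporthales",  "Sordariomycetes",  "Ascomycota"),
    c("Ustilago",        "Ustilaginaceae",    "Ustilaginales",   "Ustilaginomycetes","Basidiomycota"),
    c("Puccinia",        "Pucciniaceae",      "Pucciniales",     "Pucciniomycetes",  "Basidiomycota"),
    c("Penicillium",     "Aspergillaceae",    "Eurotiales",      "Eurotiomycetes",   "Ascomycota"),
    c("Talaromyces",     "Trichocomaceae",    "Eurotiales",      "Eurotiomycetes",   "Ascomycota"),
    c("Paecilomyces",    "Thermoascaceae",    "Eurotiales",      "Eurotiomycetes",   "Ascomycota"),
    c("Chaetomium",      "Chaetomiaceae",     "Sordariales",     "Sordariomycetes",  "Ascomycota"),
    c("Humicola",        "Chaetomiaceae",     "Sordariales",     "Sordariomycetes",  "Ascomycota"),
    c("Thielavia",       "Chaetomiaceae",     "Sordariales",     "Sordariomycetes",  "Ascomycota"),
    c("Mortierella",     "Mortierellaceae",   "Mortierellales",  "Mortierellomycetes","Mortierellomycota"),
    c("Coprinellus",     "Psathyrellaceae",   "Agaricales",      "Agaricomycetes",   "Basidiomycota"),
    c("Glomus",          "Glomeraceae",       "Glomerales",      "Glomeromycetes",   "Glomeromycota"),
    c("Rhizophagus",     "Glomeraceae",       "Glomerales",      "Glomeromycetes",   "Glomeromycota"),
    c("Funneliformis",   "Glomeraceae",       "Glomerales",      "Glomeromycetes",   "Glomeromycota"),
    c("Sebacina",        "Sebacinaceae",      "Sebacinales",     "Agaricomycetes",   "Basidiomycota"),
    c("Serendipita",     "Serendipitaceae",   "Sebacinales",     "Agaricomycetes",   "Basidiomycota"),
    c("Tuber",           "Tuberaceae",        "Pezizales",       "Pezizomycetes",    "Ascomycota"),
    c("Phoma",           "Didymellaceae",     "Pleosporales",    "Dothideomycetes",  "Ascomycota"),
    c("Macrophomina",    "Botryosphaeriaceae","Botryosphaeriales","Dothideomycetes", "Ascomycota"),
    c("Stemphylium",     "Pleosporaceae",     "Pleosporales",    "Dothideomycetes",  "Ascomycota"),
    c("Setophoma",       "Phaeosphaeriaceae", "Pleosporales",    "Dothideomycetes",  "Ascomycota"),
    c("Colletotrichum",  "Glomerellaceae",    "Glomerellales",   "Sordariomycetes",  "Ascomycota"),
    c("Olpidium",        "Olpidiaceae",       "Olpidiales",      "Chytridiomycetes", "Chytridiomycota"),
    c("Moesziomyces",    "Ustilaginaceae",    "Ustilaginales",   "Ustilaginomycetes","Basidiomycota"),
    c("Trichoderma",     "Hypocreaceae",      "Hypocreales",     "Sordariomycetes",  "Ascomycota"),
    c("Clonostachys",    "Bionectriaceae",    "Hypocreales",     "Sordariomycetes",  "Ascomycota"),
    c("Phialocephala",   "Mollisiaceae",      "Helotiales",      "Leotiomycetes",    "Ascomycota"),
    c("Cladophialophora","Herpotrichiellaceae","Chaetothyriales","Eurotiomycetes",   "Ascomycota"),
    c("Fusarium",        "Nectriaceae",       "Hypocreales",     "Sordariomycetes",  "Ascomycota"),
    c("Aspergillus",     "Aspergillaceae",    "Eurotiales",      "Eurotiomycetes",   "Ascomycota"),
    c("Alternaria",      "Pleosporaceae",     "Pleosporales",    "Dothideomycetes",  "Ascomycota"),
    c("Cladosporium",    "Cladosporiaceae",   "Capnodiales",     "Dothideomycetes",  "Ascomycota"),
    c("Rhizoctonia",     "Ceratobasidiaceae", "Cantharellales",  "Agaricomycetes",   "Basidiomycota"),
    c("Phomopsis",       "Diaporthaceae",     "Diaporthales",    "Sordariomycetes",  "Ascomycota"),
    c("Acremonium",      "Hypocreales_fam",   "Hypocreales",     "Sordariomycetes",  "Ascomycota"),
    c("Mucor",           "Mucoraceae",        "Mucorales",       "Mucoromycetes",    "Mucoromycota"),
    c("Epicoccum",       "Didymellaceae",     "Pleosporales",    "Dothideomycetes",  "Ascomycota"),
    c("Curvibasidium",   "Microbotryomycetes_fam", "Sporidiobolales", "Microbotryomycetes", "Basidiomycota"),
    c("Nigrospora",      "Trichosphaeriaceae","Trichosphaeriales","Sordariomycetes", "Ascomycota")
  )
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(df) <- c("genus", "family", "order", "class", "phylum")
  df
})

# soil-chemistry baselines: mean and sd on each variable's natural scale
# (pH unitless; C, N as %; P, NO3, NH4 as mg/kg), anchored to the sandy
# ferruginous topsoils of the groundnut basin
.SOIL_BASELINES <- list(
  pH_H2O = c(6.2, 0.30), total_C = c(0.50, 0.12), total_N = c(0.035, 0.008),
  C_N = c(13, 2.0), total_P = c(70, 15), assimilable_P = c(9, 3),
  NO3 = c(6, 2.0), NH4 = c(4, 1.5)
)

#' Simulation configuration
#'
#' Defines the simulated study: a `sum(plots_per_site) * 2 * n_reps`-sample
#' design over `n_sites` sites and 2 plant types, uneven library sizes,
#' long-tail OTU abundances, planted correlation blocks and hub OTUs,
#' log-scale site/plant effects, a per-plant-type trophic-group mixture,
#' and planted soil-trophic correlations.
#'
#' @param n_sites Number of sites (default 3).
#' @param plots_per_site Integer vector of plots per site (recycled if
#'   scalar; default `c(2, 3, 1)`).
#' @param n_reps Replicates per plot and plant type (default 5).
#' @param n_otus Number of OTUs (default 600; scalable to thousands).
#' @param depth_range Library-size bounds, drawn log-uniformly (default
#'   `c(25556, 154517)`).
#' @param block_spec List of `list(size, rho, sign)` correlated OTU blocks.
#'   `sign = 1` plants uniformly positive within-block correlation;
#'   `sign = -1` alternates signs so roughly half the block's pairs are
#'   negatively correlated.
#' @param hub_spec List of `list(n_partners, rho)` hub-and-spoke factors:
#'   one hub OTU correlated at `rho` with each partner (partner pairs then
#'   correlate at `rho^2`).
#' @param site_effect_sd,plant_effect_sd Log-scale per-OTU effect sds.
#' @param diversity_effect Dominance tilt applied to wild samples (base
#'   means raised to `1 + diversity_effect` and renormalized), lowering
#'   wild evenness/richness; 0 disables.
#' @param guild_mix Named 7-column matrix (rows `cultivated`, `wild`) of
#'   trophic-group proportions; each row sums to 1.
#' @param unassigned_frac Fraction of OTUs left without a resolvable guild.
#' @param soil_corr_spec List of `list(var, group, r)` planted per-site
#'   Pearson correlations between a soil variable and a trophic group's
#'   relative abundance.
#' @param nb_dispersion Negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param lognormal_sdlog sd of the log-normal base abundances.
#' @param seed Master seed.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_sites = 3,
                       plots_per_site = c(2, 3, 1),
                       n_reps = 5,
                       n_otus = 600,
                       depth_range = c(25556, 154517),
                       block_spec = list(list(size = 12, rho = 0.85, sign = 1),
                                         list(size = 10, rho = 0.8, sign = 1),
                                         list(size = 8, rho = 0.75, sign = 1),
                                         list(size = 10, rho = 0.85, sign = -1)),
                       hub_spec = list(list(n_partners = 15, rho = 0.85),
                                       list(n_partners = 12, rho = 0.8)),
                       site_effect_sd = 1.0,
                       plant_effect_sd = 0.3,
                       diversity_effect = 0.2,
                       guild_mix = rbind(
                         cultivated = c(Pathotroph = 0.42, Saprotroph = 0.24,
                                        Symbiotroph = 0.04, Pat_Sap = 0.03,
                                        Pat_Sym = 0.02, Sap_Sym = 0.14,
                                        Pat_Sap_Sym = 0.11),
                         wild = c(Pathotroph = 0.34, Saprotroph = 0.32,
                                  Symbiotroph = 0.04, Pat_Sap = 0.03,
                                  Pat_Sym = 0.02, Sap_Sym = 0.14,
                                  Pat_Sap_Sym = 0.11)),
                       unassigned_frac = 0.27,
                       soil_corr_spec = list(
                         list(var = "total_P", group = "Pathotroph", r = -0.6),
                         list(var = "total_P", group = "Saprotroph", r = 0.6),
                         list(var = "pH_H2O", group = "Saprotroph", r = 0.4)),
                       nb_dispersion = 0.5,
                       lognormal_sdlog = 2,
                       seed = 1) {
  if (length(plots_per_site) == 1) plots_per_site <- rep(plots_per_site, n_sites)
  cfg <- structure(list(
    n_sites = n_sites, n_plant_types = 2L, plots_per_site = plots_per_site,
    n_reps = n_reps, n_otus = n_otus, depth_range = depth_range,
    block_spec = block_spec, hub_spec = hub_spec,
    site_effect_sd = site_effect_sd, plant_effect_sd = plant_effect_sd,
    diversity_effect = diversity_effect, guild_mix = guild_mix,
    unassigned_frac = unassigned_frac, soil_corr_spec = soil_corr_spec,
    nb_dispersion = nb_dispersion, lognormal_sdlog = lognormal_sdlog,
    seed = seed
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Errors name the offending field.
#'
#' @param cfg A `sim_config`.
#' @return `cfg`, invisibly.
#' @export
validate_sim_config <- function(cfg) {
  .assert(cfg$n_sites >= 1, "n_sites: must be >= 1")
  .assert(length(cfg$plots_per_site) == cfg$n_sites,
          "plots_per_site: must have one entry per site")
  .assert(all(cfg$plots_per_site >= 1), "plots_per_site: all entries must be >= 1")
  .assert(cfg$n_reps >= 1, "n_reps: must be >= 1")
  .assert(cfg$n_otus >= 2, "n_otus: must be >= 2")
  .assert(length(cfg$depth_range) == 2 && cfg$depth_range[1] >= 1 &&
            cfg$depth_range[1] <= cfg$depth_range[2],
          "depth_range: must satisfy 1 <= lower <= upper")
  for (b in cfg$block_spec) {
    .assert(is.list(b) && all(c("size", "rho", "sign") %in% names(b)),
            "block_spec: entries need size, rho, sign")
    .assert(b$size >= 2, "block_spec: block size must be >= 2")
    .assert(abs(b$rho) < 1, "block_spec: |rho| must be < 1")
    .assert(b$sign %in% c(-1, 1), "block_spec: sign must be -1 or 1")
  }
  for (h in cfg$hub_spec) {
    .assert(is.list(h) && all(c("n_partners", "rho") %in% names(h)),
            "hub_spec: entries need n_partners, rho")
    .assert(h$n_partners >= 1, "hub_spec: n_partners must be >= 1")
    .assert(abs(h$rho) < 1, "hub_spec: |rho| must be < 1")
  }
  planted <- sum(vapply(cfg$block_spec, function(b) b$size, numeric(1))) +
    sum(vapply(cfg$hub_spec, function(h) h$n_partners + 1, numeric(1)))
  .assert(cfg$n_otus >= planted,
          "n_otus: must be >= %d, the total of block and hub OTUs", planted)
  .assert(cfg$site_effect_sd >= 0, "site_effect_sd: must be >= 0")
  .assert(cfg$plant_effect_sd >= 0, "plant_effect_sd: must be >= 0")
  .assert(cfg$diversity_effect >= 0, "diversity_effect: must be >= 0")
  gm <- cfg$guild_mix
  .assert(is.matrix(gm) && nrow(gm) == 2 &&
            setequal(colnames(gm), TROPHIC_GROUPS) &&
            setequal(rownames(gm), c("cultivated", "wild")),
          "guild_mix: must be a 2 x 7 matrix (cultivated/wild x trophic groups)")
  .assert(all(gm >= 0 & gm <= 1), "guild_mix: proportions must lie in [0, 1]")
  .assert(all(abs(rowSums(gm) - 1) < 1e-8), "guild_mix: rows must sum to 1")
  .assert(cfg$unassigned_frac >= 0 && cfg$unassigned_frac < 1,
          "unassigned_frac: must lie in [0, 1)")
  for (sc in cfg$soil_corr_spec) {
    .assert(is.list(sc) && all(c("var", "group", "r") %in% names(sc)),
            "soil_corr_spec: entries need var, group, r")
    .assert(sc$var %in% SOIL_VARIABLES, "soil_corr_spec: unknown soil variable '%s'", sc$var)
    .assert(sc$group %in% TROPHIC_GROUPS, "soil_corr_spec: unknown trophic group '%s'", sc$group)
    .assert(abs(sc$r) < 1, "soil_corr_spec: |r| must be < 1")
  }
  .assert(cfg$nb_dispersion > 0, "nb_dispersion: must be > 0")
  .assert(cfg$lognormal_sdlog >= 0, "lognormal_sdlog: must be >= 0")
  .assert(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed: must be a single number")
  invisible(cfg)
}

# project a symmetric matrix to the nearest positive semi-definite
# correlation-like matrix (eigenvalue clipping + unit-diagonal rescale)
.nearest_psd <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  out <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(pmax(diag(out), .Machine$double.eps))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  (out + t(out)) / 2
}

#' Correlated negative-binomial count vectors via a Gaussian copula
#'
#' Draws `n_samples` multivariate-normal vectors with correlation `corr`,
#' probability-transforms them, applies per-OTU negative-binomial quantile
#' functions with the given marginal means and dispersion, and (optionally)
#' subsamples each vector multinomially to `depth` reads.
#'
#' @param marginal_means Positive vector of target marginal means.
#' @param dispersion Negative-binomial size parameter (larger = closer to
#'   Poisson).
#' @param corr Correlation matrix (symmetric, unit diagonal). A non-PSD
#'   matrix is projected to the nearest PSD correlation with a warning.
#' @param n_samples Number of samples to draw.
#' @param depth Library size(s) for multinomial subsampling; scalar,
#'   vector, or `NULL` for raw negative-binomial counts.
#' @param seed Integer seed.
#' @return Integer count matrix (OTUs x samples).
#' @export
correlated_counts <- function(marginal_means, dispersion, corr,
                              n_samples, depth = NULL, seed = NULL) {
  p <- length(marginal_means)
  .assert(all(marginal_means > 0), "marginal_means must be positive")
  .assert(dispersion > 0, "dispersion must be positive")
  .assert(is.matrix(corr) && nrow(corr) == p && ncol(corr) == p,
          "corr must be a %d x %d matrix", p, p)
  .assert(isTRUE(all.equal(corr, t(corr), tolerance = 1e-8)), "corr must be symmetric")
  .assert(all(abs(diag(corr) - 1) < 1e-8), "corr must have a unit diagonal")
  ev_min <- min(eigen(corr, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8) {
    .warn("corr is not positive semi-definite (min eigenvalue %.3g); projecting to the nearest PSD correlation", ev_min)
    corr <- .nearest_psd(corr)
  }
  L <- chol(corr + diag(1e-10, p))
  if (!is.null(depth)) {
    depth <- as.integer(rep_len(depth, n_samples))
    .assert(all(depth >= 1), "depth must be >= 1")
  }
  with_seed(seed, {
    Z <- matrix(stats::rnorm(n_samples * p), n_samples, p) %*% L
    U <- stats::pnorm(Z)
    X <- vapply(seq_len(p), function(i) {
      stats::qnbinom(U[, i], size = dispersion, mu = marginal_means[i])
    }, numeric(n_samples))
    X <- t(matrix(X, nrow = n_samples))  # OTUs x samples
    if (is.null(depth)) {
      out <- X
    } else {
      out <- vapply(seq_len(n_samples), function(j) {
        x <- X[, j]
        if (sum(x) == 0) x[which.max(marginal_means)] <- 1
        as.integer(stats::rmultinom(1, depth[j], prob = x))
      }, integer(p))
    }
  })
  storage.mode(out) <- "integer"
  rownames(out) <- names(marginal_means) %||% paste0("OTU_", seq_len(p))
  colnames(out) <- paste0("S", seq_len(n_samples))
  out
}

# build the planted correlation matrix and its ground-truth records; each
# planted OTU also carries a single-factor loading used to give the block a
# shared (habitat-filtering-style) site response downstream
.planted_correlation <- function(cfg) {
  p <- cfg$n_otus
  R <- diag(p)
  membership <- rep(NA_integer_, p)
  loading <- rep(0, p)
  hubs <- integer(0)
  pair_rows <- list()
  nxt <- 1L
  for (bi in seq_along(cfg$block_spec)) {
    b <- cfg$block_spec[[bi]]
    idx <- nxt:(nxt + b$size - 1L)
    s <- if (b$sign > 0) rep(1, b$size) else rep_len(c(1, -1), b$size)
    blk <- b$rho * tcrossprod(s)
    diag(blk) <- 1
    R[idx, idx] <- blk
    membership[idx] <- bi
    loading[idx] <- s * sqrt(b$rho)
    ut <- which(upper.tri(blk), arr.ind = TRUE)
    pair_rows[[length(pair_rows) + 1L]] <- data.frame(
      otu_i = idx[ut[, 1]], otu_j = idx[ut[, 2]], rho = blk[ut])
    nxt <- nxt + b$size
  }
  for (hi in seq_along(cfg$hub_spec)) {
    h <- cfg$hub_spec[[hi]]
    hub <- nxt
    partners <- (nxt + 1L):(nxt + h$n_partners)
    idx <- c(hub, partners)
    a <- c(1, rep(h$rho, h$n_partners))  # single-factor loadings
    blk <- tcrossprod(a)
    diag(blk) <- 1
    R[idx, idx] <- blk
    membership[idx] <- length(cfg$block_spec) + hi
    loading[idx] <- a
    hubs <- c(hubs, hub)
    ut <- which(upper.tri(blk), arr.ind = TRUE)
    pair_rows[[length(pair_rows) + 1L]] <- data.frame(
      otu_i = idx[ut[, 1]], otu_j = idx[ut[, 2]], rho = blk[ut])
    nxt <- nxt + h$n_partners + 1L
  }
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(otu_i = integer(0), otu_j = integer(0), rho = numeric(0))
  list(R = R, membership = membership, loading = loading,
       n_planted = nxt - 1L, hubs = hubs, pairs = pairs)
}

# genus pools per trophic group, from the packaged lookup
.genus_pools <- function(guild_db) {
  accepted <- tolower(trimws(guild_db$confidenceRanking)) %in% ACCEPTED_CONFIDENCE
  grp <- suppressWarnings(trophic_group(guild_db$trophicMode))
  pools <- split(guild_db$taxon[accepted], grp[accepted])
  pools$rejected <- guild_db$taxon[!accepted]
  pools
}

#' Generate a complete synthetic dataset with ground truth
#'
#' Produces a count table (column sums equal the drawn library sizes),
#' sample metadata with soil chemistry, a taxonomy table, a guild lookup,
#' per-OTU guild annotations, and the planted ground truth. Identical
#' configurations (including the seed) reproduce identical output.
#'
#' @param cfg A [sim_config()].
#' @return List: `counts`, `metadata`, `taxonomy`, `guild_db`,
#'   `annotations`, `truth` (fields `block_membership`, `planted_hubs`,
#'   `planted_pairwise_rho`, `effect_table`, `soil_links`).
#' @export
generate_dataset <- function(cfg) {
  validate_sim_config(cfg)
  p <- cfg$n_otus
  otu_ids <- sprintf("OTU_%04d", seq_len(p))
  sites <- if (cfg$n_sites == 3) DEFAULT_SITES else paste0("Site", seq_len(cfg$n_sites))

  # sample skeleton: site / plot / plant type / replicate
  plot_site <- rep(seq_len(cfg$n_sites), cfg$plots_per_site)
  skeleton <- do.call(rbind, lapply(seq_along(plot_site), function(pl) {
    expand.grid(plot = paste0("P", pl), site = sites[plot_site[pl]],
                plant_type = c("cultivated", "wild"),
                rep = seq_len(cfg$n_reps),
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }))
  n <- nrow(skeleton)
  metadata <- data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                         site = skeleton$site, plant_type = skeleton$plant_type,
                         plot = skeleton$plot, stringsAsFactors = FALSE)

  # trophic groups and taxonomy
  guild_db <- builtin_guild_db()
  pools <- .genus_pools(guild_db)
  avail_groups <- intersect(TROPHIC_GROUPS, names(pools))
  mix_avg <- colMeans(cfg$guild_mix)[avail_groups]
  group <- with_seed(child_seed(cfg$seed, "groups"), {
    g <- sample(avail_groups, p, replace = TRUE, prob = mix_avg / sum(mix_avg))
    n_un <- round(cfg$unassigned_frac * p)
    if (n_un > 0) g[sample.int(p, n_un)] <- "Unassigned"
    g
  })
  genus <- with_seed(child_seed(cfg$seed, "taxonomy"), {
    vapply(group, function(g) {
      if (g == "Unassigned") {
        if (stats::runif(1) < 0.5 && length(pools$rejected)) {
          sample(pools$rejected, 1)
        } else NA_character_
      } else sample(pools[[g]], 1)
    }, character(1), USE.NAMES = FALSE)
  })
  li <- match(genus, .GENUS_LINEAGE$genus)
  taxonomy <- data.frame(
    otu_id = otu_ids, kingdom = "Fungi",
    phylum = .GENUS_LINEAGE$phylum[li], class = .GENUS_LINEAGE$class[li],
    order = .GENUS_LINEAGE$order[li], family = .GENUS_LINEAGE$family[li],
    genus = genus, species = NA_character_, stringsAsFactors = FALSE)

  planted <- .planted_correlation(cfg)

  # base means: long-tail log-normal; planted (block/hub) OTUs receive
  # evenly spaced ranks in the upper abundance tier so they are prevalent
  # enough to enter the core, as the paper's co-occurring taxa are
  base <- with_seed(child_seed(cfg$seed, "means"), {
    draw <- exp(stats::rnorm(p, 0, cfg$lognormal_sdlog))
    ms <- sort(draw, decreasing = TRUE)
    np <- planted$n_planted
    out <- numeric(p)
    if (np > 0) {
      hi <- max(np + 5L, ceiling(p / 3))
      sel <- unique(round(seq(5, min(hi, p), length.out = np)))
      while (length(sel) < np) sel <- sort(unique(c(sel, max(sel) + 1L)))
      out[seq_len(np)] <- ms[sel[seq_len(np)]]
      out[(np + 1L):p] <- ms[-sel[seq_len(np)]]
    } else {
      out <- draw
    }
    out
  })

  # site/plant effects: planted OTUs share a per-block site response scaled
  # by their factor loading (habitat filtering keeps their co-occurrence
  # visible across sites), independent OTUs respond idiosyncratically
  eff <- with_seed(child_seed(cfg$seed, "effects"), {
    site_eff <- matrix(stats::rnorm(p * cfg$n_sites, 0, cfg$site_effect_sd),
                       p, cfg$n_sites, dimnames = list(otu_ids, sites))
    n_grp <- max(c(0L, planted$membership), na.rm = TRUE)
    if (n_grp > 0) {
      grp_site <- matrix(stats::rnorm(n_grp * cfg$n_sites, 0, cfg$site_effect_sd),
                         n_grp, cfg$n_sites)
      for (i in which(!is.na(planted$membership))) {
        site_eff[i, ] <- planted$loading[i] * grp_site[planted$membership[i], ] +
          stats::rnorm(cfg$n_sites, 0, 0.3 * cfg$site_effect_sd)
      }
    }
    plant_eff <- stats::rnorm(p, 0, cfg$plant_effect_sd)
    list(site = site_eff, plant = plant_eff)
  })
  effect_table <- data.frame(otu_id = otu_ids, eff$site,
                             plant_cultivated = eff$plant,
                             check.names = FALSE, stringsAsFactors = FALSE)

  # per-plant-type base profiles: dominance tilt for wild, then group
  # multipliers steering expected trophic-group shares toward guild_mix
  profile <- list(cultivated = base / sum(base),
                  wild = { w <- base^(1 + cfg$diversity_effect); w / sum(w) })
  for (pt in names(profile)) {
    m <- profile[[pt]]
    assigned <- group != "Unassigned"
    share <- tapply(m[assigned], factor(group[assigned], levels = avail_groups), sum)
    share[is.na(share) | share == 0] <- NA
    mult <- cfg$guild_mix[pt, avail_groups] / (share / sum(share, na.rm = TRUE))
    mult[is.na(mult)] <- 1
    scale_vec <- rep(1, p)
    scale_vec[assigned] <- mult[group[assigned]]
    profile[[pt]] <- m * scale_vec
  }

  L <- chol(planted$R + diag(1e-10, p))

  depths <- with_seed(child_seed(cfg$seed, "depths"), {
    as.integer(round(exp(stats::runif(n, log(cfg$depth_range[1]),
                                      log(cfg$depth_range[2])))))
  })

  counts <- with_seed(child_seed(cfg$seed, "counts"), {
    Z <- matrix(stats::rnorm(n * p), n, p) %*% L
    U <- stats::pnorm(Z)
    out <- matrix(0L, p, n, dimnames = list(otu_ids, metadata$sample_id))
    for (j in seq_len(n)) {
      mu <- profile[[metadata$plant_type[j]]] *
        exp(eff$site[, metadata$site[j]] +
              (metadata$plant_type[j] == "cultivated") * eff$plant)
      mu <- mu / sum(mu) * 5e4
      x <- stats::qnbinom(U[j, ], size = cfg$nb_dispersion, mu = mu)
      if (sum(x) == 0) x[which.max(mu)] <- 1
      out[, j] <- as.integer(stats::rmultinom(1, depths[j], prob = x))
    }
    out
  })

  annotations <- assign_guilds(taxonomy, guild_db)

  # soil chemistry correlated with realized trophic-group abundances
  abund <- suppressWarnings(group_relative_abundance(counts, annotations))
  soil <- generate_soil(metadata, abund, cfg$soil_corr_spec,
                        seed = child_seed(cfg$seed, "soil"))

  truth <- list(
    block_membership = stats::setNames(planted$membership, otu_ids),
    planted_hubs = otu_ids[planted$hubs],
    planted_pairwise_rho = data.frame(
      otu_i = otu_ids[planted$pairs$otu_i],
      otu_j = otu_ids[planted$pairs$otu_j],
      rho = planted$pairs$rho, stringsAsFactors = FALSE),
    effect_table = effect_table,
    soil_links = soil$links,
    depths = stats::setNames(depths, metadata$sample_id)
  )
  list(counts = counts, metadata = soil$metadata, taxonomy = taxonomy,
       guild_db = guild_db, annotations = annotations, truth = truth)
}

#' Generate soil-chemistry vectors with planted trophic correlations
#'
#' Fills the soil columns of a metadata skeleton. Within each site, a
#' variable named in `soil_corr_spec` is built as
#' `r * z(group abundance) + sqrt(1 - r^2) * noise`, scaled to the
#' variable's natural baseline, so its within-site Pearson correlation
#' with the group's relative abundance targets `r`. Unspecified variables
#' are independent noise around site-shifted baselines. Realized per-site
#' correlations are reported.
#'
#' @param metadata Metadata skeleton (`sample_id`, `site`, ...).
#' @param group_abund Samples x trophic-group abundance matrix aligned to
#'   `metadata$sample_id`.
#' @param soil_corr_spec List of `list(var, group, r)` targets.
#' @param seed Integer seed.
#' @return List: `metadata` (with soil columns), `links` (data.frame
#'   `site`, `soil_var`, `group`, `target_r`, `realized_r`).
#' @export
generate_soil <- function(metadata, group_abund, soil_corr_spec, seed = NULL) {
  .assert(all(metadata$sample_id %in% rownames(group_abund)),
          "group_abund must cover all metadata samples")
  ga <- group_abund[metadata$sample_id, , drop = FALSE]
  targets <- list()
  for (sc in soil_corr_spec) {
    .assert(sc$var %in% SOIL_VARIABLES, "unknown soil variable '%s'", sc$var)
    .assert(sc$group %in% colnames(ga), "unknown trophic group '%s'", sc$group)
    targets[[sc$var]] <- sc
  }
  n <- nrow(metadata)
  sites <- unique(metadata$site)
  links <- list()
  with_seed(seed, {
    for (v in SOIL_VARIABLES) {
      bl <- .SOIL_BASELINES[[v]]
      vals <- numeric(n)
      site_shift <- stats::rnorm(length(sites), 0, 0.75) * bl[2]
      for (si in seq_along(sites)) {
        idx <- which(metadata$site == sites[si])
        eps <- stats::rnorm(length(idx))
        if (!is.null(targets[[v]])) {
          tg <- targets[[v]]
          g <- ga[idx, tg$group]
          z <- if (stats::sd(g, na.rm = TRUE) > 0) as.numeric(scale(g)) else eps * 0
          z[!is.finite(z)] <- 0
          core <- tg$r * z + sqrt(1 - tg$r^2) * eps
          links[[length(links) + 1L]] <- data.frame(
            site = sites[si], soil_var = v, group = tg$group, target_r = tg$r,
            realized_r = suppressWarnings(stats::cor(core, g,
                                                     use = "complete.obs")),
            stringsAsFactors = FALSE)
        } else {
          core <- eps
        }
        vals[idx] <- bl[1] + site_shift[si] + bl[2] * core
      }
      metadata[[v]] <- vals
    }
  })
  list(metadata = metadata,
       links = if (length(links)) do.call(rbind, links) else
         data.frame(site = character(0), soil_var = character(0),
                    group = character(0), target_r = numeric(0),
                    realized_r = numeric(0)))
}

#' Write a simulated dataset to a directory
#'
#' Emits the same TSV dialects the readers consume, plus
#' `ground_truth.json` (block membership, planted hubs and pairwise rho,
#' effect table, soil links, library sizes).
#'
#' @param dataset Output of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    guild_db = file.path(dir, "guild_db.tsv"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  write_count_table(dataset$counts, paths["counts"])
  utils::write.table(dataset$metadata, paths["metadata"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$taxonomy, paths["taxonomy"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$guild_db, paths["guild_db"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(dataset$truth, paths["ground_truth"], digits = NA,
                       dataframe = "columns", auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
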