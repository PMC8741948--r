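# Simulator: configuration validation, determinism, copula behaviour,
# planted structure, soil generation.

test_that("default design yields 60 samples with library sizes in range", {
  cfg <- sim_config(n_otus = 100, seed = 1)
  ds <- generate_dataset(cfg)
  expect_equal(ncol(ds$counts), 60)
  expect_equal(nrow(ds$metadata), 60)
  totals <- colSums(ds$counts)
  expect_true(all(totals >= 25556 & totals <= 154517))
  # column sums equal the drawn library sizes
  expect_equal(unname(totals), unname(ds$truth$depths))
  # 2 plant types x 6 plots x 5 replicates
  expect_equal(sort(unique(ds$metadata$plant_type)), c("cultivated", "wild"))
  expect_equal(length(unique(ds$metadata$plot)), 6)
  expect_equal(as.integer(table(ds$metadata$plant_type)), c(30L, 30L))
})

test_that("identical configurations reproduce every artifact exactly", {
  cfg <- sim_config(n_otus = 80, plots_per_site = 1, n_reps = 2,
                    depth_range = c(1000, 3000), seed = 99)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$taxonomy, b$taxonomy)
  expect_identical(a$truth, b$truth)

  dir_a <- withr::local_tempdir(); dir_b <- withr::local_tempdir()
  write_dataset(a, dir_a); write_dataset(b, dir_b)
  for (f in c("counts.tsv", "metadata.tsv", "taxonomy.tsv", "ground_truth.json")) {
    expect_identical(readLines(file.path(dir_a, f)), readLines(file.path(dir_b, f)))
  }
})

test_that("invalid configurations name the offending field", {
  expect_error(sim_config(depth_range = c(500, 100)), "depth_range")
  expect_error(sim_config(block_spec = list(list(size = 4, rho = 1.2, sign = 1))),
               "block_spec")
  expect_error(sim_config(n_otus = 10), "n_otus")
  expect_error(sim_config(unassigned_frac = 1.2), "unassigned_frac")
  gm_bad <- rbind(cultivated = c(Pathotroph = 0.9, Saprotroph = 0.4,
                                 Symbiotroph = 0, Pat_Sap = 0, Pat_Sym = 0,
                                 Sap_Sym = 0, Pat_Sap_Sym = 0),
                  wild = c(Pathotroph = 1, Saprotroph = 0, Symbiotroph = 0,
                           Pat_Sap = 0, Pat_Sym = 0, Sap_Sym = 0, Pat_Sap_Sym = 0))
  expect_error(sim_config(guild_mix = gm_bad), "guild_mix")
  expect_error(sim_config(soil_corr_spec = list(list(var = "unobtainium",
                                                     group = "Pathotroph", r = 0.5))),
               "soil variable")
})

test_that("identity copula produces near-zero pairwise rank correlations", {
  # ~95% of null pairs satisfy |r| < 0.2 at n = 100; average over replicates
  rates <- vapply(1:10, function(s) {
    cnt <- correlated_counts(rep(30, 20), 1, diag(20), n_samples = 100, seed = s)
    r <- cor(t(cnt), method = "spearman")
    mean(abs(r[upper.tri(r)]) < 0.2)
  }, numeric(1))
  expect_gte(mean(rates), 0.93)
})

test_that("an extreme planted pair dominates all pairwise correlations", {
  wins <- 0; reps <- 30
  for (i in seq_len(reps)) {
    R <- diag(6); R[1, 2] <- R[2, 1] <- 0.99
    cnt <- correlated_counts(rep(40, 6), 1, R, n_samples = 60, seed = 1000 + i)
    r <- cor(t(cnt), method = "spearman")
    pairs <- which(upper.tri(r), arr.ind = TRUE)
    vals <- r[upper.tri(r)]
    top <- pairs[which.max(vals), ]
    if (all(sort(top) == c(1, 2))) wins <- wins + 1
  }
  expect_gte(wins / reps, 0.95)
})

test_that("large dispersion approaches the Poisson variance-mean ratio", {
  cnt <- correlated_counts(rep(50, 3), 1e6, diag(3), n_samples = 1000, seed = 8)
  ratios <- apply(cnt, 1, var) / apply(cnt, 1, mean)
  expect_true(all(abs(ratios - 1) < 0.1))
})

test_that("non-PSD correlation inputs are projected with a warning", {
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.9
  R[1, 3] <- R[3, 1] <- 0.9
  R[2, 3] <- R[3, 2] <- -0.9   # impossible triple
  expect_warning(cnt <- correlated_counts(rep(20, 3), 1, R, n_samples = 10, seed = 9),
                 "projecting")
  expect_equal(dim(cnt), c(3L, 10L))
})

test_that("within-block rank correlations exceed 0.6 on average over replicates", {
  mean_r <- vapply(1:20, function(i) {
    cnt <- correlated_counts(rep(50, 30), 0.5, block_corr(30, 10, 0.9),
                             n_samples = 30, depth = 5000, seed = 1100 + i)
    r <- cor(t(cnt[1:10, ]), method = "spearman")
    mean(r[upper.tri(r)])
  }, numeric(1))
  expect_gt(mean(mean_r), 0.6)
})

test_that("null datasets give no spuriously persistent hub OTUs", {
  gm <- rbind(cultivated = c(Pathotroph = 0.4, Saprotroph = 0.3,
                             Symbiotroph = 0.05, Pat_Sap = 0.04, Pat_Sym = 0.02,
                             Sap_Sym = 0.09, Pat_Sap_Sym = 0.1),
              wild = c(Pathotroph = 0.4, Saprotroph = 0.3, Symbiotroph = 0.05,
                       Pat_Sap = 0.04, Pat_Sym = 0.02, Sap_Sym = 0.09,
                       Pat_Sap_Sym = 0.1))
  calls <- list()
  reps <- 25
  for (i in seq_len(reps)) {
    cfg <- sim_config(n_otus = 60, plots_per_site = 1, n_reps = 2,
                      depth_range = c(3000, 5000),
                      block_spec = list(), hub_spec = list(),
                      site_effect_sd = 0, plant_effect_sd = 0,
                      diversity_effect = 0, guild_mix = gm, seed = 1200 + i)
    ds <- generate_dataset(cfg)
    net <- suppressWarnings(build_network(ds$counts))
    if (nrow(net$nodes) == 0) next
    hubs <- identify_hubs(node_metrics(net), 0.2)$hubs
    for (h in hubs) calls[[h]] <- (calls[[h]] %||% 0) + 1
  }
  if (length(calls) > 0) {
    expect_lt(max(unlist(calls)) / reps, 0.2)
  } else {
    expect_length(calls, 0)
  }
})

test_that("soil generator plants per-site correlations and validates names", {
  set.seed(71)
  n <- 60
  md <- data.frame(sample_id = sprintf("S%03d", 1:n),
                   site = rep(c("A", "B", "C"), each = 20),
                   plant_type = "wild", plot = "P1", stringsAsFactors = FALSE)
  ab <- matrix(runif(n * 2), n, 2,
               dimnames = list(md$sample_id, c("Pathotroph", "Saprotroph")))
  spec <- list(list(var = "total_P", group = "Pathotroph", r = 0.8))
  out <- generate_soil(md, ab, spec, seed = 5)
  expect_true(all(SOIL_VARIABLES <- c("pH_H2O", "total_C", "total_N", "C_N",
                                      "total_P", "assimilable_P", "NO3", "NH4")
                  %in% names(out$metadata)))
  expect_equal(nrow(out$links), 3)  # one per site
  for (s in unique(md$site)) {
    idx <- md$site == s
    r <- cor(out$metadata$total_P[idx], ab[idx, "Pathotroph"])
    expect_gt(r, 0.5)
  }
  expect_error(generate_soil(md, ab, list(list(var = "total_P", group = "Virotroph",
                                               r = 0.5)), seed = 1),
               "unknown trophic group")
})

test_that("planted soil-trophic correlation of 0.8 is recovered at n = 20", {
  hits <- 0; reps <- 30
  for (i in seq_len(reps)) {
    set.seed(1300 + i)
    md <- data.frame(sample_id = sprintf("S%03d", 1:20), site = "Dya",
                     plant_type = "wild", plot = "P1", stringsAsFactors = FALSE)
    ab <- matrix(runif(20), 20, 1, dimnames = list(md$sample_id, "Pathotroph"))
    out <- generate_soil(md, ab, list(list(var = "total_P", group = "Pathotroph",
                                           r = 0.8)), seed = 1300 + i)
    if (cor(out$metadata$total_P, ab[, 1]) > 0.5) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)
})

test_that("empty soil spec gives independent site-centred noise", {
  md <- data.frame(sample_id = sprintf("S%03d", 1:40),
                   site = rep(c("A", "B"), each = 20),
                   plant_type = "wild", plot = "P1", stringsAsFactors = FALSE)
  ab <- matrix(runif(40), 40, 1, dimnames = list(md$sample_id, "Pathotroph"))
  out <- generate_soil(md, ab, list(), seed = 11)
  expect_equal(nrow(out$links), 0)
  # within-site z-scores of distinct variables are uncorrelated in expectation
  z <- scale(out$metadata$total_C[md$site == "A"])
  z2 <- scale(out$metadata$NH4[md$site == "A"])
  expect_lt(abs(cor(z, z2)), 0.5)
})

test_that("null design is exchangeable: PERMANOVA rejects at the nominal rate", {
  gm <- rbind(cultivated = c(Pathotroph = 0.4, Saprotroph = 0.3,
                             Symbiotroph = 0.05, Pat_Sap = 0.04, Pat_Sym = 0.02,
                             Sap_Sym = 0.09, Pat_Sap_Sym = 0.1),
              wild = c(Pathotroph = 0.4, Saprotroph = 0.3, Symbiotroph = 0.05,
                       Pat_Sap = 0.04, Pat_Sym = 0.02, Sap_Sym = 0.09,
                       Pat_Sap_Sym = 0.1))
  reps <- 100; rej <- 0
  for (i in seq_len(reps)) {
    cfg <- sim_config(n_otus = 40, plots_per_site = 1, n_reps = 2,
                      depth_range = c(1000, 2000),
                      block_spec = list(), hub_spec = list(),
                      site_effect_sd = 0, plant_effect_sd = 0,
                      diversity_effect = 0, guild_mix = gm, seed = 1400 + i)
    ds <- generate_dataset(cfg)
    pm <- permanova(bray_curtis(ds$counts), ds$metadata, terms = "plant_type",
                    permutations = 59, seed = i)
    if (pm$p[1] <= 0.05) rej <- rej + 1
  }
  expect_gte(rej / reps, 0.01)
  expect_lte(rej / reps, 0.11)
})
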