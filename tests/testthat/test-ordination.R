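# Bray-Curtis, NMDS, PERMANOVA, dispersion homogeneity, envfit, BH-FDR.

test_that("bray_curtis matches closed forms and vegan", {
  m <- cbind(a = c(1, 1, 0), b = c(0, 1, 1), c = c(1, 1, 0))
  rownames(m) <- paste0("o", 1:3)
  d <- as.matrix(bray_curtis(m))
  expect_equal(d["a", "b"], 0.5)   # (1+0+1)/4
  expect_equal(d["a", "c"], 0)     # identical samples
  disj <- cbind(x = c(5, 0), y = c(0, 7)); rownames(disj) <- c("o1", "o2")
  expect_equal(as.vector(bray_curtis(disj)), 1)

  set.seed(21)
  big <- matrix(rpois(200, 8), 20, 10,
                dimnames = list(paste0("o", 1:20), paste0("s", 1:10)))
  expect_equal(as.matrix(bray_curtis(big)),
               as.matrix(vegan::vegdist(t(big), method = "bray")),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(bray_curtis(cbind(a = c(0, 0), b = c(1, 1))), "all-zero")
})

test_that("bray_curtis is symmetric with zero diagonal on random tables", {
  set.seed(22)
  for (i in 1:10) {
    m <- matrix(rpois(60, 5) + 1, 10, 6,
                dimnames = list(paste0("o", 1:10), paste0("s", 1:6)))
    dm <- as.matrix(bray_curtis(m))
    expect_equal(dm, t(dm))
    expect_true(all(diag(dm) == 0))
    expect_true(all(dm >= 0 & dm <= 1))
  }
})

test_that("NMDS embeds planar configurations at near-zero stress", {
  set.seed(23)
  X <- matrix(rnorm(10), 5, 2)
  d <- dist(X)
  o <- nmds(d, k = 2, n_restarts = 10, seed = 1)
  expect_lt(o$stress, 0.01)
})

test_that("NMDS stress is close to an independent reference implementation", {
  set.seed(24)
  m <- matrix(rpois(300, 6), 30, 10,
              dimnames = list(paste0("o", 1:30), paste0("s", 1:10)))
  d <- bray_curtis(m)
  mine <- nmds(d, k = 2, n_restarts = 20, seed = 2)
  ref <- vegan::metaMDS(d, k = 2, trace = 0)
  expect_lt(abs(mine$stress - ref$stress), 0.02)
})

test_that("duplicate samples receive coincident NMDS scores", {
  set.seed(25)
  m <- matrix(rpois(150, 6), 30, 5,
              dimnames = list(paste0("o", 1:30), paste0("s", 1:5)))
  m <- cbind(m, s6 = m[, 5])
  d <- bray_curtis(m)
  o <- nmds(d, k = 2, n_restarts = 10, seed = 3)
  expect_lt(sqrt(sum((o$points["s5", ] - o$points["s6", ])^2)),
            0.05 * max(dist(o$points)))
})

test_that("NMDS stress decreases with embedding dimension", {
  set.seed(26)
  for (i in 1:3) {
    m <- matrix(rpois(240, 6), 30, 8,
                dimnames = list(paste0("o", 1:30), paste0("s", 1:8)))
    d <- bray_curtis(m)
    s2 <- nmds(d, k = 2, n_restarts = 10, seed = i)$stress
    s7 <- nmds(d, k = 7, n_restarts = 10, seed = i)$stress
    expect_lte(s7, s2 + 1e-8)
  }
})

test_that("PERMANOVA reproduces the 60-sample design degrees of freedom", {
  cfg <- sim_config(n_otus = 80, seed = 31)
  ds <- generate_dataset(cfg)
  d <- bray_curtis(ds$counts)
  pm <- permanova(d, ds$metadata, permutations = 19, seed = 1)
  expect_equal(pm$df, c(2, 1, 2, 54, 59))
  expect_equal(sum(pm$R2[1:4]), 1)
  expect_equal(pm$R2[5], 1)
  expect_equal(sum(pm$SS[1:4]), pm$SS[5])
})

test_that("PERMANOVA agrees with adonis2 on F and R2", {
  set.seed(32)
  m <- matrix(rpois(360, 7), 30, 12,
              dimnames = list(paste0("o", 1:30), paste0("s", 1:12)))
  md <- data.frame(sample_id = colnames(m),
                   site = rep(c("A", "B", "C"), each = 4),
                   plant_type = rep(c("cultivated", "wild"), 6),
                   stringsAsFactors = FALSE)
  d <- bray_curtis(m)
  pm <- permanova(d, md, terms = c("site", "plant_type"),
                  permutations = 99, seed = 1)
  ref <- vegan::adonis2(d ~ site + plant_type, data = md, permutations = 99,
                        by = "terms")
  expect_equal(pm$F[1:2], ref$F[1:2], tolerance = 1e-10)
  expect_equal(pm$R2[1:2], ref$R2[1:2], tolerance = 1e-10)
  expect_equal(pm$df[1:2], ref$Df[1:2])
})

test_that("PERMANOVA permutation p matches exhaustive enumeration on 6-sample toys", {
  set.seed(33)
  m <- matrix(rpois(60, 6) + 1, 10, 6,
              dimnames = list(paste0("o", 1:10), paste0("s", 1:6)))
  md <- data.frame(sample_id = colnames(m),
                   group = rep(c("a", "b"), each = 3), stringsAsFactors = FALSE)
  d <- bray_curtis(m)
  pm <- permanova(d, md, terms = "group", permutations = "exact")

  # oracle: Anderson's direct within-group formula over all 6! relabelings
  dm <- as.matrix(d)
  F_obs <- permanova_oracle_F(dm, md$group)
  expect_equal(pm$F[1], F_obs, tolerance = 1e-10)
  perms <- all_perms(1:6)
  F_all <- apply(perms, 1, function(p) permanova_oracle_F(dm[p, p], md$group))
  p_exact <- mean(F_all >= F_obs - 1e-12)
  expect_equal(pm$p[1], p_exact, tolerance = 1e-12)
})

test_that("PERMANOVA results are invariant to sample reordering", {
  set.seed(34)
  m <- matrix(rpois(240, 7), 20, 12,
              dimnames = list(paste0("o", 1:20), paste0("s", 1:12)))
  md <- data.frame(sample_id = colnames(m),
                   site = rep(c("A", "B", "C"), each = 4), stringsAsFactors = FALSE)
  d1 <- bray_curtis(m)
  ord <- sample(ncol(m))
  d2 <- bray_curtis(m[, ord])
  p1 <- permanova(d1, md, terms = "site", permutations = 49, seed = 9)
  p2 <- permanova(d2, md, terms = "site", permutations = 49, seed = 9)
  expect_equal(p1$F[1], p2$F[1], tolerance = 1e-10)
  expect_equal(p1$R2, p2$R2, tolerance = 1e-10)
  expect_error(permanova(d1, data.frame(sample_id = colnames(m), g = "x"),
                         terms = "g"), "single level")
})

test_that("dispersion test matches centroid distances and symmetry null", {
  set.seed(35)
  m <- matrix(rpois(300, 8), 30, 10,
              dimnames = list(paste0("o", 1:30), paste0("s", 1:10)))
  d <- bray_curtis(m)
  g <- rep(c("a", "b"), each = 5)
  mine <- group_dispersion(d, g, n_perm = 99, seed = 1)
  ref <- vegan::betadisper(d, g, type = "centroid")
  expect_equal(unname(mine$distances), unname(ref$distances), tolerance = 1e-10)
  expect_equal(mine$F, anova(ref)$`F value`[1], tolerance = 1e-10)

  # identical samples: all distances zero
  same <- matrix(5L, 4, 6, dimnames = list(paste0("o", 1:4), paste0("s", 1:6)))
  ds <- group_dispersion(bray_curtis(same), rep(c("a", "b"), 3),
                         n_perm = 19, seed = 2)
  expect_true(all(ds$distances == 0))

  expect_warning(
    group_dispersion(d, c(rep("a", 5), rep("b", 4), "c"), n_perm = 19, seed = 3),
    "singleton")
})

test_that("dispersion test detects inflated within-group spread", {
  hits <- 0; reps <- 25
  for (i in seq_len(reps)) {
    set.seed(400 + i)
    base <- matrix(rpois(20 * 10, 20), 20, 10)
    noisy <- matrix(rnbinom(20 * 10, mu = 20, size = 0.4), 20, 10)
    m <- cbind(base, noisy)
    dimnames(m) <- list(paste0("o", 1:20), paste0("s", 1:20))
    m[m < 0] <- 0
    storage.mode(m) <- "integer"
    g <- rep(c("tight", "loose"), each = 10)
    res <- group_dispersion(bray_curtis(m), g, n_perm = 99, seed = i)
    if (res$p <= 0.05) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)
})

test_that("envfit recovers exact axis alignments and flags constants", {
  set.seed(36)
  scores <- matrix(rnorm(40), 20, 2,
                   dimnames = list(paste0("s", 1:20), c("NMDS1", "NMDS2")))
  md <- data.frame(sample_id = rownames(scores),
                   pH_H2O = scores[, 1],
                   total_P = -scores[, 2],
                   NO3 = rep(1, 20), stringsAsFactors = FALSE)
  expect_warning(
    ef <- fit_env_vectors(scores, md, variables = c("pH_H2O", "total_P", "NO3"),
                          n_perm = 99, seed = 1),
    "constant")
  expect_equal(ef$r2[1], 1, tolerance = 1e-10)
  expect_equal(unlist(ef[1, c("NMDS1", "NMDS2")]), c(NMDS1 = 1, NMDS2 = 0),
               tolerance = 1e-8)
  expect_equal(ef$r2[2], 1, tolerance = 1e-10)
  expect_equal(unlist(ef[2, c("NMDS1", "NMDS2")]), c(NMDS1 = 0, NMDS2 = -1),
               tolerance = 1e-8)
  expect_equal(ef$r2[3], 0)
  expect_equal(ef$p[3], 1)
})

test_that("envfit r2 matches vegan on noisy data", {
  set.seed(37)
  scores <- matrix(rnorm(40), 20, 2,
                   dimnames = list(paste0("s", 1:20), c("NMDS1", "NMDS2")))
  md <- data.frame(sample_id = rownames(scores),
                   total_C = scores[, 1] + rnorm(20), stringsAsFactors = FALSE)
  ef <- fit_env_vectors(scores, md, variables = "total_C", n_perm = 99, seed = 1)
  ref <- vegan::envfit(scores, md["total_C"], permutations = 99)
  expect_equal(ef$r2, unname(ref$vectors$r), tolerance = 1e-10)
})

test_that("BH adjustment matches the step-up hand computation", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  # hand-computed step-up: sorted p * n/rank, cummin from the top, capped
  p <- c(0.005, 0.011, 0.02, 0.04, 0.9)
  expect_equal(bh_fdr(p), c(0.025, 0.0275, 0.03333333, 0.05, 0.9),
               tolerance = 1e-6)
  expect_true(all(bh_fdr(p) >= p))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})
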