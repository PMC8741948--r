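# Shared fixtures, built in code.

# small deterministic count matrix (OTUs x samples)
toy_counts <- function(n_otu = 6, n_samp = 4, seed = 1, lambda = 20) {
  set.seed(seed)
  m <- matrix(rpois(n_otu * n_samp, lambda), n_otu, n_samp,
              dimnames = list(sprintf("OTU_%02d", seq_len(n_otu)),
                              sprintf("S%02d", seq_len(n_samp))))
  storage.mode(m) <- "integer"
  m
}

toy_metadata <- function(sample_ids, plant = NULL, site = NULL) {
  n <- length(sample_ids)
  data.frame(
    sample_id = sample_ids,
    site = site %||% rep_len(c("Dya", "Nioro"), n),
    plant_type = plant %||% rep_len(c("cultivated", "wild"), n),
    plot = rep_len(paste0("P", 1:2), n),
    pH_H2O = seq(5.5, 7, length.out = n),
    total_P = seq(50, 90, length.out = n),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-built network objects for closed-form topology checks
make_network <- function(edges_df, node_ids = NULL) {
  ids <- node_ids %||% sort(unique(c(edges_df$source, edges_df$target)))
  structure(list(
    nodes = data.frame(otu_id = ids,
                       abundance = rep(1 / max(length(ids), 1), length(ids)),
                       trophic_group = rep(NA_character_, length(ids)),
                       guild = rep(NA_character_, length(ids)),
                       stringsAsFactors = FALSE),
    edges = edges_df, label = NULL,
    pct_positive = if (nrow(edges_df)) 100 * mean(edges_df$sign == "positive") else NA_real_,
    n_samples = 10, n_otus_tested = length(ids)),
    class = "cooccurrence_network")
}

star_network <- function(n_leaves = 4) {
  make_network(data.frame(source = "hub", target = paste0("leaf", seq_len(n_leaves)),
                          r = 0.9, q = 1e-4, sign = "positive",
                          stringsAsFactors = FALSE))
}

path_network <- function() {
  make_network(data.frame(source = c("A", "B"), target = c("B", "C"),
                          r = 0.8, q = 1e-4, sign = "positive",
                          stringsAsFactors = FALSE))
}

two_triangles_network <- function() {
  make_network(data.frame(source = c("a", "b", "a", "d", "e", "d"),
                          target = c("b", "c", "c", "e", "f", "f"),
                          r = 0.8, q = 1e-4, sign = "positive",
                          stringsAsFactors = FALSE))
}

# hub-and-spoke correlation matrix: OTU 1 correlated at rho with the next
# n_partners OTUs (single-factor construction), remainder independent
hub_corr <- function(n_otus, n_partners, rho) {
  R <- diag(n_otus)
  a <- c(1, rep(rho, n_partners))
  blk <- tcrossprod(a); diag(blk) <- 1
  R[seq_len(n_partners + 1), seq_len(n_partners + 1)] <- blk
  R
}

# block correlation matrix: first `size` OTUs at uniform within-block rho
block_corr <- function(n_otus, size, rho) {
  R <- diag(n_otus)
  R[seq_len(size), seq_len(size)] <- rho
  diag(R) <- 1
  R
}

# one-way PERMANOVA computed directly from within-group distance sums
# (Anderson's closed form) -- independent oracle for the trace-based path
permanova_oracle_F <- function(dm, groups) {
  n <- nrow(dm)
  a <- length(unique(groups))
  d2 <- dm^2
  ss_tot <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ss_between <- ss_tot - ss_within
  (ss_between / (a - 1)) / (ss_within / (n - a))
}

all_perms <- function(v) {
  if (length(v) <= 1) return(matrix(v, 1))
  out <- NULL
  for (i in seq_along(v)) {
    sub <- all_perms(v[-i])
    out <- rbind(out, cbind(v[i], sub))
  }
  out
}
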