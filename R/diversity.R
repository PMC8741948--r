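# Rarefaction normalization and per-sample alpha-diversity indices.

#' Rarefy a count table to equal depth
#'
#' Each sample is subsampled *without replacement* (multivariate
#' hypergeometric) to exactly `depth` reads, the classic `rarefy`-style
#' normalization used to remove library-size bias before diversity and
#' co-occurrence analyses. Samples with fewer than `depth` reads are
#' dropped with a warning. A single draw is taken (not an average over
#' repeated draws); the seed makes it reproducible.
#'
#' @param counts Integer count matrix (OTUs x samples).
#' @param depth Target depth (reads per sample), >= 1.
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return Rarefied count matrix; every column sums to `depth`.
#' @export
#' @examples
#' m <- matrix(c(100L, 50L, 30L, 70L), 2, 2,
#'             dimnames = list(c("o1", "o2"), c("s1", "s2")))
#' colSums(rarefy_counts(m, 40, seed = 1))
rarefy_counts <- function(counts, depth, seed = NULL) {
  .check_count_matrix(counts)
  .assert(length(depth) == 1 && depth >= 1 && depth == floor(depth),
          "depth must be a single integer >= 1")
  totals <- colSums(counts)
  keep <- totals >= depth
  if (!any(keep)) .stop("all samples have fewer than %d reads", depth)
  if (any(!keep)) {
    .warn("dropping %d sample(s) below depth %d: %s",
          sum(!keep), depth, paste(colnames(counts)[!keep], collapse = ", "))
  }
  counts <- counts[, keep, drop = FALSE]
  n_otu <- nrow(counts)
  with_seed(seed, {
    out <- vapply(seq_len(ncol(counts)), function(j) {
      x <- counts[, j]
      if (sum(x) == depth) return(x)
      reads <- rep.int(seq_len(n_otu), x)
      drawn <- sample(reads, depth, replace = FALSE)
      tabulate(drawn, nbins = n_otu)
    }, integer(n_otu))
  })
  out <- matrix(as.integer(out), nrow = n_otu, dimnames = dimnames(counts))
  out
}

#' Shannon diversity index (natural log)
#'
#' `H = -sum(p_i * log(p_i))` over the non-zero proportions of a sample's
#' count vector, in nats.
#'
#' @param counts Non-negative count (or proportion) vector, not all zero.
#' @return Shannon index.
#' @export
#' @examples
#' shannon(c(25, 25, 25, 25))  # log(4)
shannon <- function(counts) {
  p <- .proportions(counts)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Gini-Simpson diversity index
#'
#' Returns `1 - D` with `D = sum(p_i^2)` (the probability that two reads
#' drawn at random belong to the same OTU); in `[0, 1)`. Set
#' `gini = FALSE` for the raw concentration `D`.
#'
#' @param counts Non-negative count vector, not all zero.
#' @param gini Return `1 - D` (default) rather than `D`.
#' @return Diversity value.
#' @export
#' @examples
#' simpson(c(25, 25, 25, 25))  # 0.75
simpson <- function(counts, gini = TRUE) {
  p <- .proportions(counts)
  d <- sum(p^2)
  if (gini) 1 - d else d
}

#' Observed richness
#'
#' Number of OTUs with a non-zero count.
#'
#' @param counts Non-negative count vector, not all zero.
#' @return Integer count of observed OTUs.
#' @export
richness <- function(counts) {
  .proportions(counts)  # validates
  sum(counts > 0)
}

.proportions <- function(counts) {
  .assert(is.numeric(counts) && length(counts) >= 1, "counts must be a numeric vector")
  .assert(all(is.finite(counts)) && all(counts >= 0), "counts must be finite and non-negative")
  s <- sum(counts)
  .assert(s > 0, "all-zero count vector")
  counts / s
}

#' Per-sample alpha-diversity table
#'
#' One row per sample with observed richness, Shannon (nats), Gini-Simpson
#' and raw Simpson concentration, joined with the sample's site, plant type
#' and plot. The exported table is exactly what a downstream mixed-model
#' refit (plant type and site as fixed effects, plot as random) would
#' consume.
#'
#' @param counts Rarefied count matrix (OTUs x samples).
#' @param metadata Metadata data.frame ([read_metadata()] layout).
#' @return data.frame with columns `sample_id`, `site`, `plant_type`,
#'   `plot`, `richness`, `shannon`, `simpson`, `simpson_D`.
#' @export
alpha_table <- function(counts, metadata) {
  .check_count_matrix(counts)
  validate_dataset(counts, metadata, strict = FALSE)
  idx <- match(colnames(counts), metadata$sample_id)
  data.frame(
    sample_id = colnames(counts),
    site = metadata$site[idx],
    plant_type = metadata$plant_type[idx],
    plot = metadata$plot[idx],
    richness = apply(counts, 2, richness),
    shannon = apply(counts, 2, shannon),
    simpson = apply(counts, 2, simpson),
    simpson_D = apply(counts, 2, simpson, gini = FALSE),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
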