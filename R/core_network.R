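# Prevalence-based core-mycobiome extraction, Spearman co-occurrence
# networks with FDR-controlled edges, graph topology, hub calling and
# cross-network comparison.

#' Extract the prevalence-based core mycobiome
#'
#' An OTU belongs to the core when it is present (count >= 1) in at least
#' `prevalence_threshold` of all pooled samples (boundary inclusive; the
#' classic choice is 75%). Richness and read shares are reported against
#' the full table.
#'
#' @param counts Rarefied count matrix (OTUs x samples), all samples pooled.
#' @param prevalence_threshold Fraction in (0, 1] (default 0.75).
#' @return Object of class `core_set`: `otu_ids`, `prevalence` (named, core
#'   OTUs), `share_of_richness`, `share_of_reads`, `always_present_ids`,
#'   `n_total_otus`, `threshold`.
#' @export
core_mycobiome <- function(counts, prevalence_threshold = 0.75) {
  .check_count_matrix(counts)
  .assert(length(prevalence_threshold) == 1 && prevalence_threshold > 0 &&
            prevalence_threshold <= 1,
          "prevalence_threshold must lie in (0, 1]")
  prevalence <- rowMeans(counts > 0)
  keep <- prevalence >= prevalence_threshold
  core_ids <- rownames(counts)[keep]
  structure(list(
    otu_ids = core_ids,
    prevalence = prevalence[keep],
    share_of_richness = length(core_ids) / nrow(counts),
    share_of_reads = sum(counts[keep, , drop = FALSE]) / sum(counts),
    always_present_ids = rownames(counts)[prevalence == 1],
    n_total_otus = nrow(counts),
    threshold = prevalence_threshold
  ), class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf(paste0(
    "Core mycobiome at %.0f%% prevalence: %d of %d OTUs\n",
    "  %s%% of observed richness, %s%% of reads; %d OTU(s) in every sample\n"),
    100 * x$threshold, length(x$otu_ids), x$n_total_otus,
    format(share_pct(length(x$otu_ids), x$n_total_otus), nsmall = 1),
    format(round(100 * x$share_of_reads, 1), nsmall = 1),
    length(x$always_present_ids)))
  invisible(x)
}

#' Summarize a core set as a one-row data.frame
#'
#' Shares are reported as percentages rounded to one decimal, the
#' convention used in the results tables.
#'
#' @param object A `core_set`.
#' @param ... Unused.
#' @return One-row data.frame.
#' @export
summary.core_set <- function(object, ...) {
  data.frame(
    n_core = length(object$otu_ids),
    n_total = object$n_total_otus,
    n_always_present = length(object$always_present_ids),
    richness_share_pct = share_pct(length(object$otu_ids), object$n_total_otus),
    reads_share_pct = round(100 * object$share_of_reads, 1)
  )
}

# Spearman rho for all OTU pairs plus two-sided p via the t approximation
# with average-rank tie handling (the standard large-sample treatment).
.spearman_matrix <- function(m) {
  # m: samples x OTUs
  n <- nrow(m)
  r <- stats::cor(m, method = "spearman")
  t_stat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  p[abs(abs(r) - 1) < 1e-12] <- 0
  list(r = r, p = p)
}

#' Build a Spearman co-occurrence network
#'
#' Computes Spearman's rank correlation (average-rank ties) for every
#' unordered OTU pair within one stratum (e.g. the core table restricted
#' to one plant type), BH-adjusts the two-sided p values over all pairs
#' of this network, and keeps edges with `|r| > r_threshold` and
#' `q < alpha`. Nodes with no surviving edge are dropped; OTUs constant
#' across the stratum are excluded from correlation with a warning.
#'
#' @param counts Count matrix (core OTUs x stratum samples), >= 4 samples.
#' @param r_threshold Correlation magnitude threshold (default 0.6).
#' @param alpha FDR threshold on adjusted p (default 0.01).
#' @param annotations Optional [assign_guilds()] table for node guild and
#'   trophic-group attributes.
#' @param label Optional network label (e.g. the plant type).
#' @return Object of class `cooccurrence_network`: `nodes` (data.frame
#'   `otu_id`, `abundance` proportional abundance in the stratum,
#'   `trophic_group`, `guild`), `edges` (`source`, `target`, `r`, `q`,
#'   `sign`), `label`, `pct_positive`, `n_samples`, `n_otus_tested`.
#' @export
build_network <- function(counts, r_threshold = 0.6, alpha = 0.01,
                          annotations = NULL, label = NULL) {
  .check_count_matrix(counts, min_dim = 2)
  .assert(ncol(counts) >= 4, "need at least 4 samples to build a network")
  .assert(r_threshold >= 0 && r_threshold < 1, "r_threshold must lie in [0, 1)")
  .assert(alpha > 0 && alpha <= 1, "alpha must lie in (0, 1]")
  constant <- apply(counts, 1, function(x) length(unique(x)) == 1)
  if (any(constant)) {
    .warn("excluding %d OTU(s) constant across the stratum", sum(constant))
    counts <- counts[!constant, , drop = FALSE]
  }
  .assert(nrow(counts) >= 2, "need at least 2 non-constant OTUs")
  sp <- .spearman_matrix(t(counts))
  ut <- which(upper.tri(sp$r), arr.ind = TRUE)
  r <- sp$r[ut]
  q <- bh_fdr(sp$p[ut])
  keep <- abs(r) > r_threshold & q < alpha
  edges <- data.frame(
    source = rownames(counts)[ut[keep, 1]],
    target = rownames(counts)[ut[keep, 2]],
    r = r[keep], q = q[keep],
    sign = ifelse(r[keep] > 0, "positive", "negative"),
    stringsAsFactors = FALSE
  )
  node_ids <- sort(unique(c(edges$source, edges$target)))
  abund <- rowSums(counts[node_ids, , drop = FALSE]) / sum(counts)
  nodes <- data.frame(otu_id = node_ids,
                      abundance = as.numeric(abund),
                      trophic_group = rep(NA_character_, length(node_ids)),
                      guild = rep(NA_character_, length(node_ids)),
                      stringsAsFactors = FALSE)
  if (!is.null(annotations) && nrow(nodes) > 0) {
    ai <- match(nodes$otu_id, annotations$otu_id)
    nodes$trophic_group <- annotations$trophic_group[ai]
    nodes$guild <- annotations$guild[ai]
  }
  structure(list(
    nodes = nodes, edges = edges, label = label,
    pct_positive = if (nrow(edges) > 0) 100 * mean(edges$sign == "positive") else NA_real_,
    n_samples = ncol(counts), n_otus_tested = nrow(counts)
  ), class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("Co-occurrence network%s: %d nodes, %d edges (%.2f%% positive), %d samples\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              nrow(x$nodes), nrow(x$edges),
              if (is.na(x$pct_positive)) 0 else x$pct_positive, x$n_samples))
  invisible(x)
}

#' Node-level topology metrics
#'
#' Degree, shortest-path betweenness (unnormalized), classic closeness
#' normalized within each connected component, and eigenvector centrality
#' on the largest component (0 elsewhere). All metrics are computed on
#' the unweighted, sign-blind graph.
#'
#' @param network A `cooccurrence_network` (or igraph graph).
#' @return data.frame: `otu_id`, `degree`, `betweenness`, `closeness`,
#'   `eigenvector`.
#' @export
node_metrics <- function(network) {
  g <- if (inherits(network, "igraph")) network else as_igraph(network)
  .assert(igraph::vcount(g) >= 1, "empty network")
  comp <- igraph::components(g)
  eig <- numeric(igraph::vcount(g))
  giant <- which(comp$membership == which.max(comp$csize))
  if (length(giant) >= 2) {
    sub <- igraph::induced_subgraph(g, giant)
    eig[giant] <- igraph::eigen_centrality(sub)$vector
  } else {
    eig[giant] <- 1
  }
  data.frame(
    otu_id = igraph::V(g)$name,
    degree = igraph::degree(g),
    betweenness = igraph::betweenness(g, directed = FALSE, normalized = FALSE),
    closeness = suppressWarnings(igraph::closeness(g, normalized = TRUE)),
    eigenvector = eig,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Network-level topology metrics
#'
#' Node and edge counts, % positive edges, average degree `2E/N`, average
#' path length and diameter over the largest connected component, density
#' `2E/(N(N-1))`, mean local clustering coefficient (degree-<2 nodes count
#' 0), and Louvain modularity at resolution 1 (best of `n_louvain` seeded
#' runs). All on the unweighted, sign-blind graph.
#'
#' @param network A `cooccurrence_network`.
#' @param seed Integer seed for the Louvain runs.
#' @param n_louvain Number of Louvain restarts (default 10).
#' @return One-row data.frame.
#' @export
network_metrics <- function(network, seed = 1, n_louvain = 10) {
  g <- if (inherits(network, "igraph")) network else as_igraph(network)
  .assert(igraph::vcount(g) >= 1 && igraph::ecount(g) >= 1, "empty network")
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  comp <- igraph::components(g)
  giant <- igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
  mods <- vapply(seq_len(n_louvain), function(i) {
    with_seed(child_seed(seed, paste0("louvain", i)), {
      igraph::modularity(igraph::cluster_louvain(g, resolution = 1))
    })
  }, numeric(1))
  pct_pos <- if (inherits(network, "cooccurrence_network")) network$pct_positive else NA_real_
  data.frame(
    n_nodes = n,
    n_edges = e,
    pct_positive = pct_pos,
    avg_degree = 2 * e / n,
    avg_path_length = igraph::mean_distance(giant),
    diameter = igraph::diameter(giant),
    density = igraph::edge_density(g),
    modularity = max(mods),
    modularity_spread = max(mods) - min(mods),
    clustering = igraph::transitivity(g, type = "localaverage", isolates = "zero")
  )
}

# top-k ids by a metric, including all ties at the rank-k value
.top_k_ids <- function(ids, metric, k) {
  cutoff <- sort(metric, decreasing = TRUE)[k]
  list(ids = ids[metric >= cutoff], cutoff = cutoff)
}

#' Identify hub OTUs from node metrics
#'
#' Hubs are the OTUs in the top `top_fraction` (default 2%) of *both*
#' degree and betweenness centrality: `k = ceiling(top_fraction * N)`
#' candidates are taken per metric (ties at rank k included), and the two
#' candidate sets are intersected (`method = "union"` unions them
#' instead). The metric cutoffs are reported.
#'
#' @param metrics data.frame from [node_metrics()].
#' @param top_fraction Fraction of nodes per metric (default 0.02).
#' @param method `"intersection"` (default) or `"union"`.
#' @return Object of class `hub_report`: `hubs`, `k`, `degree_cutoff`,
#'   `betweenness_cutoff`, `method`.
#' @export
identify_hubs <- function(metrics, top_fraction = 0.02,
                          method = c("intersection", "union")) {
  method <- match.arg(method)
  .assert(nrow(metrics) >= 1, "no nodes")
  .assert(top_fraction > 0 && top_fraction <= 1, "top_fraction must lie in (0, 1]")
  k <- ceiling(top_fraction * nrow(metrics))
  by_deg <- .top_k_ids(metrics$otu_id, metrics$degree, k)
  by_btw <- .top_k_ids(metrics$otu_id, metrics$betweenness, k)
  hubs <- if (method == "intersection") intersect(by_deg$ids, by_btw$ids) else
    union(by_deg$ids, by_btw$ids)
  structure(list(hubs = hubs, k = k,
                 degree_cutoff = by_deg$cutoff,
                 betweenness_cutoff = by_btw$cutoff,
                 method = method),
            class = "hub_report")
}

#' @export
print.hub_report <- function(x, ...) {
  cat(sprintf("Hub OTUs (%s of top-%d sets; degree >= %g, betweenness >= %g): %s\n",
              x$method, x$k, x$degree_cutoff, x$betweenness_cutoff,
              if (length(x$hubs)) paste(x$hubs, collapse = ", ") else "none"))
  invisible(x)
}

#' Compare node metrics between two networks
#'
#' Two-sided Wilcoxon rank-sum test per node metric (degree, betweenness,
#' closeness, eigenvector): exact enumeration when both networks have at
#' most 10 nodes and no ties, otherwise the normal approximation with tie
#' correction.
#'
#' @param metrics_a,metrics_b data.frames from [node_metrics()].
#' @param labels Length-2 labels for the two networks.
#' @return data.frame: `metric`, `median_<a>`, `median_<b>`, `W`, `p`.
#' @export
compare_networks <- function(metrics_a, metrics_b, labels = c("a", "b")) {
  .assert(nrow(metrics_a) >= 1 && nrow(metrics_b) >= 1, "both networks must be non-empty")
  cols <- c("degree", "betweenness", "closeness", "eigenvector")
  small <- nrow(metrics_a) <= 10 && nrow(metrics_b) <= 10
  rows <- lapply(cols, function(m) {
    a <- metrics_a[[m]]; b <- metrics_b[[m]]
    ties <- anyDuplicated(c(a, b)) > 0
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, exact = small && !ties, correct = !small))
    data.frame(metric = m,
               median_a = stats::median(a), median_b = stats::median(b),
               W = unname(wt$statistic), p = wt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[2:3] <- paste0("median_", labels)
  out
}
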