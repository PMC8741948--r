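# Guild and trophic-mode assignment from a FUNGuild-style lookup table,
# aggregation of relative abundances into the 7 trophic-mode groups (or
# finer guilds), and per-site Pearson correlations with soil properties.

TROPHIC_GROUPS <- c("Pathotroph", "Saprotroph", "Symbiotroph",
                    "Pat_Sap", "Pat_Sym", "Sap_Sym", "Pat_Sap_Sym")

ACCEPTED_CONFIDENCE <- c("highly probable", "probable")

#' Canonical trophic-mode group of a trophic-mode string
#'
#' Maps a hyphen-separated combination of `Pathotroph`, `Saprotroph` and
#' `Symbiotroph` tokens (any order, any case) onto one of the 7 canonical
#' groups: the three single modes, `Pat_Sap`, `Pat_Sym`, `Sap_Sym` and
#' `Pat_Sap_Sym`. Unknown tokens (or missing input) give `Unassigned`
#' with a warning.
#'
#' @param trophic_mode Character vector of trophic-mode strings.
#' @return Character vector of group labels.
#' @export
#' @examples
#' trophic_group("Symbiotroph-Saprotroph")  # "Sap_Sym"
trophic_group <- function(trophic_mode) {
  vapply(as.character(trophic_mode), function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return("Unassigned")
    tokens <- tolower(trimws(strsplit(s, "-", fixed = TRUE)[[1]]))
    tokens <- tokens[nzchar(tokens)]
    known <- c(pathotroph = "Pat", saprotroph = "Sap", symbiotroph = "Sym")
    if (!all(tokens %in% names(known))) {
      .warn("unknown trophic-mode token(s) in '%s'", s)
      return("Unassigned")
    }
    present <- names(known)[names(known) %in% tokens]  # canonical order
    if (length(present) == 1) {
      c(pathotroph = "Pathotroph", saprotroph = "Saprotroph",
        symbiotroph = "Symbiotroph")[[present]]
    } else {
      paste(known[present], collapse = "_")
    }
  }, character(1), USE.NAMES = FALSE)
}

#' Assign OTUs to guilds and trophic modes
#'
#' Looks each OTU up in a FUNGuild-style table at the most specific
#' taxonomic rank present in the lookup (species, then genus, family,
#' order, class, phylum, kingdom), matching names case-insensitively.
#' Assignments whose confidence ranking is not `Highly Probable` or
#' `Probable` are retained in the output but marked `Unassigned`, as are
#' OTUs with no match.
#'
#' @param taxonomy Taxonomy data.frame ([read_taxonomy()] layout).
#' @param guild_db Guild lookup data.frame ([read_guild_db()] layout).
#' @return data.frame with one row per OTU: `otu_id`, `matched_taxon`,
#'   `matched_rank`, `trophic_mode`, `guild`, `confidence`,
#'   `trophic_group`.
#' @export
assign_guilds <- function(taxonomy, guild_db) {
  .assert(all(c("otu_id", TAXONOMIC_RANKS) %in% names(taxonomy)),
          "taxonomy must carry otu_id and the canonical rank columns")
  db_key <- tolower(guild_db$taxon)
  db_level <- tolower(as.character(guild_db$taxonomicLevel))
  ranks_specific_first <- rev(TAXONOMIC_RANKS)
  n <- nrow(taxonomy)
  out <- data.frame(
    otu_id = taxonomy$otu_id,
    matched_taxon = NA_character_, matched_rank = NA_character_,
    trophic_mode = NA_character_, guild = NA_character_,
    confidence = NA_character_, trophic_group = "Unassigned",
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    for (r in ranks_specific_first) {
      name <- taxonomy[[r]][i]
      if (is.na(name) || .is_unassigned(name)) next
      hits <- which(db_key == tolower(name))
      if (length(hits) == 0) next
      # prefer a lookup row whose declared level matches the rank matched at
      exact <- hits[db_level[hits] == r]
      hit <- if (length(exact) > 0) exact[1L] else hits[1L]
      out$matched_taxon[i] <- guild_db$taxon[hit]
      out$matched_rank[i] <- r
      out$trophic_mode[i] <- guild_db$trophicMode[hit]
      out$guild[i] <- guild_db$guild[hit]
      out$confidence[i] <- guild_db$confidenceRanking[hit]
      if (tolower(trimws(guild_db$confidenceRanking[hit])) %in% ACCEPTED_CONFIDENCE) {
        out$trophic_group[i] <- suppressWarnings(trophic_group(guild_db$trophicMode[hit]))
      }
      break
    }
  }
  out
}

#' Relative abundance of trophic groups or guilds per sample
#'
#' Per sample, the proportion of reads (default) or of observed OTUs
#' (`weighted = FALSE`) belonging to each group, computed over assigned
#' OTUs only: `Unassigned` OTUs are excluded from the denominator, so
#' rows sum to 1 over the assigned groups. A sample with no assigned
#' reads gets an `NA` row with a warning.
#'
#' @param counts Rarefied count matrix (OTUs x samples).
#' @param annotations Annotation data.frame from [assign_guilds()].
#' @param level Aggregate by `"trophic_group"` (default) or `"guild"`.
#' @param weighted Read-weighted proportions (default); `FALSE` counts
#'   each observed OTU once.
#' @return Matrix (samples x groups) of proportions.
#' @export
group_relative_abundance <- function(counts, annotations,
                                     level = c("trophic_group", "guild"),
                                     weighted = TRUE) {
  level <- match.arg(level)
  .check_count_matrix(counts)
  idx <- match(rownames(counts), annotations$otu_id)
  .assert(!anyNA(idx), "annotations missing for some OTUs in the count table")
  labels <- annotations[[level]][idx]
  if (level == "guild") labels[annotations$trophic_group[idx] == "Unassigned"] <- NA
  assigned <- !is.na(labels) & labels != "Unassigned"
  .assert(any(assigned), "no assigned OTUs")
  groups <- sort(unique(labels[assigned]))
  if (level == "trophic_group") {
    groups <- TROPHIC_GROUPS[TROPHIC_GROUPS %in% groups]
  }
  m <- counts[assigned, , drop = FALSE]
  if (!weighted) m <- (m > 0) + 0L
  lab <- labels[assigned]
  agg <- t(rowsum(m, group = lab)[groups, , drop = FALSE])
  denom <- rowSums(agg)
  empty <- denom == 0
  if (any(empty)) {
    .warn("%d sample(s) have no assigned reads; returning NA rows: %s",
          sum(empty), paste(rownames(agg)[empty], collapse = ", "))
    denom[empty] <- NA
  }
  agg / denom
}

.p_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", ""))))
}

#' Pearson correlation between soil properties and trophic-group abundances
#'
#' Within each site (or pooled, with `per_site = FALSE`), computes the
#' Pearson correlation between every soil variable and the relative
#' abundance of every trophic group, with two-sided p values from the t
#' distribution on `n - 2` df. Stars code the unadjusted p
#' (`* < 0.05`, `** < 0.01`, `*** < 0.001`); a BH-adjusted column over
#' all cells is also reported. Incomplete samples are dropped pairwise;
#' cells with fewer than 3 complete pairs, or a constant vector, are NA.
#'
#' @param group_abund Matrix (samples x groups) from
#'   [group_relative_abundance()].
#' @param metadata Metadata data.frame with soil columns.
#' @param variables Soil variables to use (default: those present).
#' @param per_site Correlate within each site (default) or pooled.
#' @return Tidy data.frame: `site`, `soil_var`, `group`, `n`, `r`, `p`,
#'   `stars`, `q`.
#' @export
soil_trophic_correlation <- function(group_abund, metadata,
                                     variables = intersect(SOIL_VARIABLES, names(metadata)),
                                     per_site = TRUE) {
  .assert(is.matrix(group_abund) && !is.null(rownames(group_abund)),
          "group_abund must be a samples x groups matrix with sample row names")
  .assert(length(variables) >= 1, "no soil variables present in metadata")
  idx <- match(rownames(group_abund), metadata$sample_id)
  .assert(!anyNA(idx), "metadata missing for some samples")
  meta <- metadata[idx, , drop = FALSE]
  sites <- if (per_site) split(seq_len(nrow(meta)), meta$site) else
    list(all = seq_len(nrow(meta)))
  rows <- list()
  for (s in names(sites)) {
    rs <- sites[[s]]
    for (v in variables) {
      for (g in colnames(group_abund)) {
        x <- meta[[v]][rs]
        y <- group_abund[rs, g]
        ok <- is.finite(x) & is.finite(y)
        n_ok <- sum(ok)
        if (n_ok < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
          r <- NA_real_; p <- NA_real_
        } else {
          ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
          r <- unname(ct$estimate); p <- ct$p.value
        }
        rows[[length(rows) + 1L]] <- data.frame(
          site = s, soil_var = v, group = g, n = n_ok, r = r, p = p,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$stars <- .p_stars(out$p)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  if (any(ok)) out$q[ok] <- bh_fdr(out$p[ok])
  out
}
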