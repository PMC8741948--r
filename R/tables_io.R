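# Readers and writers for the tabular and graph formats the pipeline touches.
# The canonical table format is plain TSV: OTUs as rows, samples as columns,
# header row required. A BIOM-TSV dialect (leading "# Constructed from biom
# file" comment line) is accepted on read for interoperability.

SOIL_VARIABLES <- c("pH_H2O", "total_C", "total_N", "C_N",
                    "total_P", "assimilable_P", "NO3", "NH4")

TAXONOMIC_RANKS <- c("kingdom", "phylum", "class", "order",
                     "family", "genus", "species")

# split a TSV file into fields, with ragged-row detection reporting 1-based
# physical line numbers
.read_tsv_fields <- function(path) {
  lines <- readLines(path, warn = FALSE)
  skip <- 0L
  while (skip < length(lines) && startsWith(lines[skip + 1L], "#")) skip <- skip + 1L
  .assert(length(lines) > skip + 1L, "file '%s' has no data rows", path)
  fields <- strsplit(lines[(skip + 1L):length(lines)], "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (any(widths != widths[1L])) {
    bad <- which(widths != widths[1L])[1L]
    .stop("ragged row in '%s': line %d has %d fields, expected %d",
          path, skip + bad, widths[bad], widths[1L])
  }
  list(fields = fields, offset = skip)
}

#' Read an OTU count table from TSV
#'
#' First column holds OTU identifiers, remaining columns one sample each;
#' a header row is required. Cells must be non-negative integers; anything
#' else is rejected with the offending line and column named. A leading
#' `#`-comment line (BIOM TSV dialect) is skipped.
#'
#' @param path Path to a tab-separated count table.
#' @return Integer matrix (OTUs x samples) with OTU row names and sample
#'   column names.
#' @export
read_count_table <- function(path) {
  parsed <- .read_tsv_fields(path)
  fields <- parsed$fields
  header <- fields[[1L]]
  sample_ids <- header[-1L]
  .assert(length(sample_ids) >= 1, "count table '%s' has no sample columns", path)
  .assert(!anyDuplicated(sample_ids), "duplicate sample ids in '%s'", path)
  body <- fields[-1L]
  otu_ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(otu_ids)) {
    dup <- otu_ids[duplicated(otu_ids)][1L]
    .stop("duplicate OTU id '%s' in '%s'", dup, path)
  }
  cells <- vapply(body, function(f) f[-1L], character(length(sample_ids)))
  cells <- matrix(cells, nrow = length(sample_ids))  # samples x OTUs (char)
  ok <- matrix(grepl("^[0-9]+$", cells), nrow = nrow(cells))
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1L, ]
    .stop("invalid count '%s' at line %d (OTU '%s', sample '%s') in '%s': counts must be non-negative integers",
          cells[bad[1L], bad[2L]], parsed$offset + 1L + bad[2L],
          otu_ids[bad[2L]], sample_ids[bad[1L]], path)
  }
  counts <- t(matrix(as.integer(cells), nrow = length(sample_ids),
                     dimnames = list(sample_ids, otu_ids)))
  .check_count_matrix(counts)
}

#' Write an OTU count table to TSV
#'
#' @param counts Integer matrix (OTUs x samples).
#' @param path Output path.
#' @param id_column Header name of the OTU id column.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path, id_column = "otu_id") {
  .check_count_matrix(counts)
  df <- data.frame(otu_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Mandatory columns: `sample_id`, `site`, `plant_type`, `plot`. Soil
#' chemistry columns (`pH_H2O`, `total_C`, `total_N`, `C_N`, `total_P`,
#' `assimilable_P`, `NO3`, `NH4`) are optional, numeric, `NA` for missing
#' values. `plant_type` is normalized case-insensitively to
#' `cultivated`/`wild`. Unknown extra columns are preserved.
#'
#' @param path Path to a tab-separated metadata table.
#' @return A data.frame, one row per sample.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  for (col in c("sample_id", "site", "plant_type", "plot")) {
    .assert(col %in% names(df), "metadata '%s' is missing mandatory column '%s'", path, col)
  }
  .assert(!anyDuplicated(df$sample_id), "duplicate sample ids in metadata '%s'", path)
  df$plant_type <- tolower(trimws(df$plant_type))
  bad <- setdiff(unique(df$plant_type), c("cultivated", "wild"))
  .assert(length(bad) == 0,
          "metadata '%s': plant_type must be 'cultivated' or 'wild' (found '%s')",
          path, paste(bad, collapse = "', '"))
  df$site <- as.character(df$site)
  df$plot <- as.character(df$plot)
  for (v in intersect(SOIL_VARIABLES, names(df))) {
    df[[v]] <- suppressWarnings(as.numeric(df[[v]]))
    .assert(all(is.finite(df[[v]]) | is.na(df[[v]])),
            "metadata '%s': soil variable '%s' must be numeric or NA", path, v)
  }
  df
}

# markers treated as "unassigned" at a taxonomic rank
.is_unassigned <- function(x) {
  x <- sub("^[a-z]__", "", trimws(x))
  is.na(x) | x == "" | tolower(x) %in% c("na", "unidentified", "unassigned", "incertae_sedis")
}

#' Read a taxonomy table from TSV
#'
#' Accepts either one column per rank (`kingdom` ... `genus`, `species`
#' optional) or a single `taxonomy` column of semicolon-separated ranks
#' (`k__`-style prefixes are stripped). Unassigned ranks become `NA`.
#'
#' @param path Path to a tab-separated taxonomy table.
#' @return data.frame with `otu_id` plus the seven canonical rank columns.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  names(df) <- ifelse(tolower(names(df)) %in% c(TAXONOMIC_RANKS, "taxonomy", "otu_id"),
                      tolower(names(df)), names(df))
  .assert("otu_id" %in% names(df), "taxonomy '%s' is missing mandatory column 'otu_id'", path)
  .assert(!anyDuplicated(df$otu_id), "duplicate OTU ids in taxonomy '%s'", path)
  out <- data.frame(otu_id = as.character(df$otu_id), stringsAsFactors = FALSE)
  if ("taxonomy" %in% names(df)) {
    parts <- strsplit(as.character(df$taxonomy), ";", fixed = TRUE)
    for (i in seq_along(TAXONOMIC_RANKS)) {
      out[[TAXONOMIC_RANKS[i]]] <- vapply(parts, function(p) {
        if (length(p) >= i) trimws(p[i]) else NA_character_
      }, character(1))
    }
  } else {
    .assert(any(TAXONOMIC_RANKS %in% names(df)),
            "taxonomy '%s' needs rank columns (kingdom...species) or a 'taxonomy' column", path)
    for (r in TAXONOMIC_RANKS) {
      out[[r]] <- if (r %in% names(df)) as.character(df[[r]]) else NA_character_
    }
  }
  for (r in TAXONOMIC_RANKS) {
    v <- sub("^[a-z]__", "", trimws(out[[r]]))
    v[.is_unassigned(out[[r]])] <- NA_character_
    out[[r]] <- v
  }
  out
}

#' Read a FUNGuild-style guild lookup table
#'
#' Mandatory columns (matched case-insensitively): `taxon`,
#' `taxonomicLevel`, `trophicMode`, `guild`, `confidenceRanking`. Extra
#' columns are preserved but ignored by downstream operations.
#'
#' @param path Path to a tab-separated guild database.
#' @return data.frame with canonical column names.
#' @export
read_guild_db <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  canonical <- c(taxon = "taxon", taxonomiclevel = "taxonomicLevel",
                 trophicmode = "trophicMode", guild = "guild",
                 confidenceranking = "confidenceRanking")
  lowered <- tolower(names(df))
  for (key in names(canonical)) {
    hit <- which(lowered == key)
    .assert(length(hit) >= 1, "guild table '%s' is missing mandatory column '%s'",
            path, canonical[[key]])
    names(df)[hit[1L]] <- canonical[[key]]
  }
  df$taxon <- trimws(as.character(df$taxon))
  .assert(all(nzchar(df$taxon)), "guild table '%s' has empty taxon names", path)
  df
}

#' Read the packaged miniature guild database
#'
#' A small synthetic FUNGuild-style lookup (not the FUNGuild download)
#' covering genera observed in pearl millet roots and other common fungi;
#' used by the simulator and the test suite. Trophic modes and guild
#' strings are curated to be plausible, not authoritative.
#'
#' @return data.frame in [read_guild_db()] layout.
#' @export
builtin_guild_db <- function() {
  read_guild_db(system.file("extdata", "guild_db_mini.tsv",
                            package = "milletmyco", mustWork = TRUE))
}

#' Cross-validate a count table against its companion tables
#'
#' Every sample in the count table must have a metadata row and every OTU a
#' taxonomy row. Extra metadata/taxonomy entries are an error under
#' `strict = TRUE`, otherwise a warning.
#'
#' @param counts Count matrix (OTUs x samples).
#' @param metadata Metadata data.frame ([read_metadata()] layout).
#' @param taxonomy Optional taxonomy data.frame.
#' @param strict Treat extra metadata/taxonomy entries as errors?
#' @return `TRUE`, invisibly, or an error.
#' @export
validate_dataset <- function(counts, metadata, taxonomy = NULL, strict = TRUE) {
  .check_count_matrix(counts)
  missing_meta <- setdiff(colnames(counts), metadata$sample_id)
  .assert(length(missing_meta) == 0,
          "samples missing from metadata: %s", paste(missing_meta, collapse = ", "))
  extra_meta <- setdiff(metadata$sample_id, colnames(counts))
  if (length(extra_meta) > 0) {
    msg <- sprintf("metadata has %d sample(s) absent from the count table: %s",
                   length(extra_meta), paste(extra_meta, collapse = ", "))
    if (strict) .stop(msg) else .warn(msg)
  }
  if (!is.null(taxonomy)) {
    missing_tax <- setdiff(rownames(counts), taxonomy$otu_id)
    .assert(length(missing_tax) == 0,
            "OTUs missing from taxonomy: %s",
            paste(utils::head(missing_tax, 5), collapse = ", "))
    extra_tax <- setdiff(taxonomy$otu_id, rownames(counts))
    if (length(extra_tax) > 0) {
      msg <- sprintf("taxonomy has %d OTU(s) absent from the count table", length(extra_tax))
      if (strict) .stop(msg) else .warn(msg)
    }
  }
  invisible(TRUE)
}

#' Write a co-occurrence network to GraphML or edge CSV
#'
#' GraphML carries all node attributes (taxon, guild, trophic group,
#' proportional abundance, plus any topology columns present) and edge
#' attributes (`r`, `q`, `sign`); the edge CSV has columns
#' `source,target,r,q,sign`.
#'
#' @param network A `cooccurrence_network` (see [build_network()]).
#' @param path Output path.
#' @param format `"graphml"` or `"edge_csv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("graphml", "edge_csv")) {
  format <- match.arg(format)
  .assert(inherits(network, "cooccurrence_network"), "not a cooccurrence_network")
  if (format == "edge_csv") {
    edges <- network$edges[, c("source", "target", "r", "q", "sign")]
    utils::write.table(edges, path, sep = ",", quote = FALSE, row.names = FALSE)
  } else {
    g <- as_igraph(network)
    # igraph requires a file connection for graphml
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Convert a co-occurrence network to an igraph object
#'
#' @param network A `cooccurrence_network`.
#' @return An undirected igraph graph with node and edge attributes.
#' @export
as_igraph <- function(network) {
  .assert(inherits(network, "cooccurrence_network"), "not a cooccurrence_network")
  nodes <- network$nodes
  names(nodes)[names(nodes) == "otu_id"] <- "name"
  igraph::graph_from_data_frame(network$edges, directed = FALSE, vertices = nodes)
}
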