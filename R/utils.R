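# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.stop <- function(msg, ...) stop(sprintf(msg, ...), call. = FALSE)

.warn <- function(msg, ...) warning(sprintf(msg, ...), call. = FALSE)

.assert <- function(cond, msg, ...) {
  if (!isTRUE(cond)) .stop(msg, ...)
  invisible(TRUE)
}

#' Evaluate an expression with a temporary RNG state
#'
#' Sets the seed for the duration of `expr` and restores the caller's
#' `.Random.seed` afterwards, so package functions never clobber the user's
#' random stream. A `NULL` seed evaluates `expr` against the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive a child seed from a master seed and a stage label
#'
#' One pipeline-level seed is expanded into independent per-stage seeds by a
#' small polynomial hash over the stage label, so any stage can be re-run in
#' isolation and still reproduce its output. Results stay below 2^31 - 1.
#'
#' @param seed Master integer seed.
#' @param stage Stage label (string or integer counter).
#' @return An integer seed.
#' @export
#' @examples
#' child_seed(1, "rarefy")
child_seed <- function(seed, stage) {
  .assert(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
          "seed must be a single finite number")
  m <- 2147483647
  h <- abs(as.numeric(seed)) %% m
  for (code in utf8ToInt(paste0("stage:", stage))) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

# Percentage share rounded to one decimal, the convention used in summaries
# (e.g. a 260-OTU core of a 5524-OTU table is a 4.7% richness share).

#' Percentage share of a count within a total
#'
#' @param part Numerator count.
#' @param total Denominator count.
#' @param digits Decimal places (default 1, the reporting convention).
#' @return Percentage, rounded.
#' @export
#' @examples
#' share_pct(260, 5524)  # 4.7
share_pct <- function(part, total, digits = 1) {
  .assert(total > 0, "total must be positive")
  round(100 * part / total, digits)
}

# validate a count matrix (OTUs x samples); returns it invisibly
.check_count_matrix <- function(counts, min_dim = 1) {
  .assert(is.matrix(counts) && is.numeric(counts), "counts must be a numeric matrix")
  .assert(!is.null(rownames(counts)) && !is.null(colnames(counts)),
          "count matrix must carry OTU row names and sample column names")
  .assert(!anyDuplicated(rownames(counts)), "duplicate OTU ids in count matrix")
  .assert(!anyDuplicated(colnames(counts)), "duplicate sample ids in count matrix")
  .assert(all(is.finite(counts)) && all(counts >= 0), "counts must be finite and non-negative")
  .assert(all(counts == floor(counts)), "counts must be integers")
  .assert(nrow(counts) >= min_dim && ncol(counts) >= min_dim,
          "count matrix needs at least %d OTUs and %d samples", min_dim, min_dim)
  invisible(counts)
}
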