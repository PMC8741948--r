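# Beta-diversity statistics: Bray-Curtis dissimilarities, non-metric
# multidimensional scaling, distance-based permutation tests (PERMANOVA,
# dispersion homogeneity), environmental vector fitting, and the shared
# BH-FDR utility.

#' Bray-Curtis dissimilarity between samples
#'
#' `d(x, y) = sum|x_i - y_i| / sum(x_i + y_i)` over OTU abundances, in
#' `[0, 1]`: 0 for identical samples, 1 for disjoint supports.
#'
#' @param counts Count matrix (OTUs x samples), no all-zero sample.
#' @return A `stats::dist` object labelled with sample ids.
#' @export
bray_curtis <- function(counts) {
  .assert(is.matrix(counts) && is.numeric(counts), "counts must be a numeric matrix")
  .assert(ncol(counts) >= 2, "need at least 2 samples")
  .assert(all(is.finite(counts)) && all(counts >= 0), "counts must be finite and non-negative")
  zero <- colSums(counts) == 0
  if (any(zero)) {
    .stop("all-zero sample(s): %s", paste(colnames(counts)[zero], collapse = ", "))
  }
  n <- ncol(counts)
  d <- matrix(0, n, n)
  for (j in seq_len(n - 1)) {
    x <- counts[, j]
    rest <- counts[, (j + 1):n, drop = FALSE]
    num <- colSums(abs(rest - x))
    den <- colSums(rest + x)
    d[(j + 1):n, j] <- num / den
  }
  stats::as.dist(structure(d, dimnames = list(colnames(counts), colnames(counts))))
}

# ---------------------------------------------------------------------------
# NMDS: Kruskal stress-1 minimized by alternating monotone (isotonic)
# regression on the dissimilarity ranks with Guttman-transform configuration
# updates, over several random restarts.

# fitted monotone values for configuration distances d, in the order `ord`
# (pairs sorted by dissimilarity, ties pre-sorted by d: primary tie handling)
.monotone_fit <- function(d, ord) {
  dhat <- numeric(length(d))
  dhat[ord] <- stats::isoreg(d[ord])$yf
  dhat
}

.stress1 <- function(d, dhat) sqrt(sum((d - dhat)^2) / sum(d^2))

# one NMDS run from a given starting configuration
.nmds_run <- function(delta, X, max_iter, tol) {
  n <- nrow(X)
  ij <- which(lower.tri(diag(n)), arr.ind = TRUE)
  # primary tie treatment: within blocks of tied dissimilarities, order by
  # current d so tied pairs never constrain each other
  d <- as.vector(stats::dist(X))
  ord <- order(delta, d)
  dhat <- .monotone_fit(d, ord)
  stress <- .stress1(d, dhat)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # Guttman transform toward the monotone-fitted distances
    b <- numeric(length(d))
    pos <- d > 0
    b[pos] <- dhat[pos] / d[pos]
    B <- matrix(0, n, n)
    B[cbind(ij[, 1], ij[, 2])] <- -b
    B[cbind(ij[, 2], ij[, 1])] <- -b
    diag(B) <- -rowSums(B)
    X_new <- B %*% X / n
    d_new <- as.vector(stats::dist(X_new))
    if (all(d_new == 0)) break  # degenerate collapse
    ord <- order(delta, d_new)
    dhat_new <- .monotone_fit(d_new, ord)
    stress_new <- .stress1(d_new, dhat_new)
    if (stress_new > stress) break  # safeguard: never report an uphill step
    improved <- stress - stress_new
    X <- X_new; d <- d_new; dhat <- dhat_new; stress <- stress_new
    if (improved < tol) { converged <- TRUE; break }
  }
  list(points = X, stress = stress, converged = converged)
}

#' Non-metric multidimensional scaling
#'
#' Embeds a dissimilarity matrix in `k` dimensions by minimizing Kruskal
#' stress-1, alternating monotone regression of configuration distances on
#' the dissimilarity ranks with Guttman-transform updates. The first start
#' is metric (classical) scaling; the remaining starts are random. The
#' lowest-stress solution is returned, centred, with principal axes
#' rotated to decreasing variance.
#'
#' @param d A `dist` object or symmetric dissimilarity matrix.
#' @param k Number of dimensions (>= 2 recommended; >= 1 allowed).
#' @param n_restarts Number of starting configurations (default 20).
#' @param max_iter Iteration cap per run.
#' @param tol Stress-improvement convergence tolerance.
#' @param seed Integer seed for the random starts.
#' @return Object of class `nmds`: `points` (n x k score matrix), `stress`,
#'   `converged`, `n_restarts_used`.
#' @export
nmds <- function(d, k = 2, n_restarts = 20, max_iter = 300, tol = 1e-7, seed = NULL) {
  dm <- as.matrix(d)
  .assert(nrow(dm) >= 3, "need at least 3 samples for NMDS")
  .assert(isTRUE(all.equal(dm, t(dm))), "dissimilarity matrix must be symmetric")
  .assert(all(diag(dm) == 0), "dissimilarity matrix must have a zero diagonal")
  .assert(k >= 1 && k < nrow(dm), "k must be in [1, n-1]")
  n <- nrow(dm)
  delta <- as.vector(stats::as.dist(dm))
  .assert(any(delta > 0), "all dissimilarities are zero")
  # metric start: classical scaling (padded with small noise if deficient)
  cmd <- suppressWarnings(stats::cmdscale(dm, k = k))
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      X0 <- if (r == 1) {
        X <- matrix(0, n, k)
        X[, seq_len(ncol(cmd))] <- cmd
        X + matrix(stats::rnorm(n * k, sd = 1e-4), n, k)
      } else {
        matrix(stats::rnorm(n * k, sd = stats::sd(delta)), n, k)
      }
      run <- .nmds_run(delta, X0, max_iter, tol)
      if (is.null(best) || run$stress < best$stress) best <- run
    }
  })
  pts <- scale(best$points, center = TRUE, scale = FALSE)
  if (k > 1) pts <- pts %*% svd(pts, nu = 0)$v  # principal-axis rotation
  rownames(pts) <- rownames(dm)
  colnames(pts) <- paste0("NMDS", seq_len(k))
  structure(list(points = pts, stress = best$stress,
                 converged = best$converged, n_restarts_used = n_restarts),
            class = "nmds")
}

#' @export
print.nmds <- function(x, ...) {
  cat(sprintf("NMDS ordination: %d samples, %d dimensions, stress = %.4f (%s)\n",
              nrow(x$points), ncol(x$points), x$stress,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

# ---------------------------------------------------------------------------
# PERMANOVA

# Gower-centered inner-product matrix of a distance matrix
.gower_center <- function(dm) {
  a <- -0.5 * dm^2
  n <- nrow(a)
  C <- diag(n) - matrix(1 / n, n, n)
  C %*% a %*% C
}

# projection (hat) matrix onto the column space of X
.hat <- function(X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}

# expand a term label like "site:plant_type" into a design matrix
.term_matrix <- function(term, metadata) {
  vars <- strsplit(term, ":", fixed = TRUE)[[1]]
  f <- interaction(lapply(vars, function(v) {
    .assert(v %in% names(metadata), "unknown metadata column '%s' in PERMANOVA term", v)
    factor(metadata[[v]])
  }), drop = TRUE)
  .assert(nlevels(f) >= 2, "PERMANOVA term '%s' has a single level", term)
  stats::model.matrix(~ f)[, -1, drop = FALSE]
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions the total sum of squares of a (Gower-centered) distance
#' matrix sequentially (Type-I) across the model terms, in the order
#' given, and tests each pseudo-F statistic by permuting whole samples.
#' `p = (#\{permuted F >= observed\} + 1) / (n_perm + 1)`, so p never
#' reaches 0. `permutations = "exact"` enumerates all `n!` sample
#' relabelings (small n only) and returns the exact permutation p.
#'
#' @param d `dist` object or symmetric distance matrix.
#' @param metadata Metadata data.frame aligned with the samples of `d`
#'   (matched on `sample_id` when `d` carries labels).
#' @param terms Character vector of term labels (columns of `metadata`,
#'   `:` for interactions), tested sequentially in this order.
#' @param permutations Number of random permutations (default 999), or
#'   `"exact"` for full enumeration (n <= 8).
#' @param seed Integer seed for the permutations.
#' @return Object of class `permanova`: data.frame with one row per term
#'   plus `Residuals` and `Total`, columns `df`, `SS`, `MS`, `F`, `R2`,
#'   `p`; attribute `n_permutations`.
#' @export
permanova <- function(d, metadata, terms = c("site", "plant_type", "site:plant_type"),
                      permutations = 999, seed = NULL) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (!is.null(rownames(dm)) && "sample_id" %in% names(metadata)) {
    .assert(all(rownames(dm) %in% metadata$sample_id),
            "distance matrix samples missing from metadata")
    metadata <- metadata[match(rownames(dm), metadata$sample_id), , drop = FALSE]
  }
  .assert(nrow(metadata) == n, "metadata does not align with the distance matrix")
  G <- .gower_center(dm)
  # sequential hat matrices: intercept, then cumulative term designs
  Xs <- lapply(terms, .term_matrix, metadata = metadata)
  ones <- matrix(1, n, 1)
  cum <- ones
  H_prev <- .hat(cum)
  df <- numeric(length(terms))
  H_term <- vector("list", length(terms))
  rank_prev <- 1L
  for (i in seq_along(terms)) {
    cum <- cbind(cum, Xs[[i]])
    H <- .hat(cum)
    rank_now <- qr(cum)$rank
    df[i] <- rank_now - rank_prev
    .assert(df[i] >= 1, "PERMANOVA term '%s' is aliased with earlier terms", terms[i])
    H_term[[i]] <- H - H_prev
    H_prev <- H
    rank_prev <- rank_now
  }
  H_full <- H_prev
  df_res <- n - rank_prev
  .assert(df_res >= 1, "no residual degrees of freedom")

  f_stats <- function(Gp) {
    ss_term <- vapply(H_term, function(H) sum(H * Gp), numeric(1))
    ss_tot <- sum(diag(Gp))
    # G is Gower-centered (and stays centered under symmetric permutation),
    # so the intercept projection contributes nothing to the traces
    ss_res <- ss_tot - sum(H_full * Gp)
    list(ss = ss_term, ss_res = ss_res, ss_tot = ss_tot,
         F = (ss_term / df) / (ss_res / df_res))
  }
  obs <- f_stats(G)

  if (identical(permutations, "exact")) {
    .assert(n <= 8, "exact enumeration limited to n <= 8 samples")
    perms <- .all_permutations(n)
    Fm <- vapply(seq_len(nrow(perms)), function(i) {
      f_stats(G[perms[i, ], perms[i, ]])$F
    }, numeric(length(terms)))
    Fm <- matrix(Fm, nrow = length(terms))
    p <- rowMeans(Fm >= obs$F - 1e-12)  # identity permutation included
    n_perm <- nrow(perms)
  } else {
    .assert(is.numeric(permutations) && permutations >= 1,
            "permutations must be a positive integer or \"exact\"")
    n_perm <- as.integer(permutations)
    exceed <- numeric(length(terms))
    with_seed(seed, {
      for (b in seq_len(n_perm)) {
        idx <- sample.int(n)
        Fp <- f_stats(G[idx, idx])$F
        exceed <- exceed + (Fp >= obs$F - 1e-12)
      }
    })
    p <- (exceed + 1) / (n_perm + 1)
  }

  ss <- c(obs$ss, obs$ss_res, obs$ss_tot)
  dfs <- c(df, df_res, n - 1)
  out <- data.frame(
    term = c(terms, "Residuals", "Total"),
    df = dfs,
    SS = ss,
    MS = c(obs$ss / df, obs$ss_res / df_res, NA),
    F = c(obs$F, NA, NA),
    R2 = ss / obs$ss_tot,
    p = c(p, NA, NA),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("permanova", "data.frame"), n_permutations = n_perm)
}

.all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA (%d permutations)\n", attr(x, "n_permutations")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

# ---------------------------------------------------------------------------
# Multivariate dispersion homogeneity (betadisper-style)

#' Homogeneity of multivariate dispersions
#'
#' Embeds the distance matrix by principal coordinates (keeping negative
#' eigenvalues as an imaginary correction), computes each sample's distance
#' to its group centroid as `sqrt(max(0, d_real^2 - d_imag^2))`, and tests
#' group differences in those distances with a one-way F statistic whose p
#' value comes from permuting the distances across groups. Groups of size
#' one are kept in the output but excluded from the test with a warning.
#'
#' @param d `dist` object or symmetric distance matrix.
#' @param groups Group factor aligned with the samples.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return List of class `dispersion_test`: `distances` (per sample),
#'   `groups`, `F`, `p`, `n_permutations`.
#' @export
group_dispersion <- function(d, groups, n_perm = 999, seed = NULL) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  groups <- factor(groups)
  .assert(length(groups) == n, "groups must align with the distance matrix")
  .assert(nlevels(droplevels(groups)) >= 2, "need at least 2 groups")
  G <- .gower_center(dm)
  e <- eigen(G, symmetric = TRUE)
  pos <- e$values > sqrt(.Machine$double.eps)
  neg <- e$values < -sqrt(.Machine$double.eps)
  Xr <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]), sum(pos))
  Xi <- e$vectors[, neg, drop = FALSE] %*% diag(sqrt(-e$values[neg]), sum(neg))
  z <- numeric(n)
  for (g in levels(groups)) {
    idx <- which(groups == g)
    cr <- colMeans(Xr[idx, , drop = FALSE])
    ci <- if (ncol(Xi)) colMeans(Xi[idx, , drop = FALSE]) else numeric(0)
    dr2 <- rowSums(sweep(Xr[idx, , drop = FALSE], 2, cr)^2)
    di2 <- if (ncol(Xi)) rowSums(sweep(Xi[idx, , drop = FALSE], 2, ci)^2) else 0
    z[idx] <- sqrt(pmax(dr2 - di2, 0))
  }
  sizes <- table(groups)
  singleton <- names(sizes)[sizes < 2]
  test_mask <- !(groups %in% singleton)
  if (length(singleton) > 0) {
    .warn("excluding singleton group(s) from the dispersion test: %s",
          paste(singleton, collapse = ", "))
  }
  zt <- z[test_mask]
  gt <- droplevels(groups[test_mask])
  .assert(nlevels(gt) >= 2, "fewer than 2 groups of size >= 2")
  f_of <- function(zz) {
    fit <- stats::anova(stats::lm(zz ~ gt))
    fit$`F value`[1]
  }
  if (stats::var(zt) == 0) {
    # degenerate: identical dispersions everywhere, nothing to test
    F_obs <- NA_real_
    p <- 1
  } else {
    F_obs <- f_of(zt)
    exceed <- 0
    with_seed(seed, {
      for (b in seq_len(n_perm)) {
        if (f_of(sample(zt)) >= F_obs - 1e-12) exceed <- exceed + 1
      }
    })
    p <- (exceed + 1) / (n_perm + 1)
  }
  structure(list(distances = stats::setNames(z, rownames(dm)), groups = groups,
                 F = F_obs, p = p, n_permutations = n_perm),
            class = "dispersion_test")
}

#' @export
print.dispersion_test <- function(x, ...) {
  cat(sprintf("Multivariate dispersion homogeneity: F = %.3f, p = %.4g (%d permutations)\n",
              x$F, x$p, x$n_permutations))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Environmental vector fitting on ordination scores

#' Fit environmental vectors onto an ordination
#'
#' For each soil variable, fits a least-squares regression of the
#' (centred) variable on the ordination scores. Reports the squared
#' multiple correlation `r2`, the unit direction cosines of the fitted
#' vector on the ordination axes, and a permutation p value obtained by
#' shuffling the variable across samples. Samples with a missing value are
#' dropped pairwise (a message records how many). Constant variables get
#' `r2 = 0`, `p = 1` and a warning.
#'
#' @param ordination An `nmds` object, or a numeric score matrix.
#' @param metadata Metadata data.frame with the soil variables.
#' @param variables Which variables to fit (default: the soil chemistry
#'   columns present in `metadata`).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return data.frame of class `envfit_result`: one row per variable with
#'   direction cosines (one column per axis), `r2` and `p`.
#' @export
fit_env_vectors <- function(ordination, metadata,
                            variables = intersect(SOIL_VARIABLES, names(metadata)),
                            n_perm = 999, seed = NULL) {
  S <- if (inherits(ordination, "nmds")) ordination$points else as.matrix(ordination)
  n <- nrow(S)
  if (!is.null(rownames(S)) && "sample_id" %in% names(metadata)) {
    .assert(all(rownames(S) %in% metadata$sample_id),
            "ordination samples missing from metadata")
    metadata <- metadata[match(rownames(S), metadata$sample_id), , drop = FALSE]
  }
  .assert(nrow(metadata) == n, "metadata does not align with the ordination")
  .assert(length(variables) >= 1, "no variables to fit")
  Sc <- scale(S, center = TRUE, scale = FALSE)
  k <- ncol(Sc)
  rows <- lapply(variables, function(v) {
    .assert(v %in% names(metadata), "unknown variable '%s'", v)
    x <- as.numeric(metadata[[v]])
    ok <- is.finite(x)
    if (sum(!ok) > 0) {
      message(sprintf("fit_env_vectors: dropping %d sample(s) with missing '%s'",
                      sum(!ok), v))
    }
    xs <- x[ok]
    Ss <- scale(S[ok, , drop = FALSE], center = TRUE, scale = FALSE)
    if (length(xs) < k + 2 || stats::sd(xs) == 0) {
      .warn("variable '%s' is constant or has too few complete samples", v)
      return(c(rep(0, k), r2 = 0, p = 1))
    }
    xc <- xs - mean(xs)
    fit_r2 <- function(xv) {
      b <- qr.coef(qr(Ss), xv)
      b[is.na(b)] <- 0
      fitted <- Ss %*% b
      list(b = b, r2 = sum(fitted^2) / sum(xv^2))
    }
    obs <- fit_r2(xc)
    dir <- if (sum(obs$b^2) > 0) obs$b / sqrt(sum(obs$b^2)) else rep(0, k)
    exceed <- 0
    with_seed(if (is.null(seed)) NULL else child_seed(seed, v), {
      for (b in seq_len(n_perm)) {
        xp <- sample(xc)
        if (fit_r2(xp)$r2 >= obs$r2 - 1e-12) exceed <- exceed + 1
      }
    })
    c(dir, r2 = obs$r2, p = (exceed + 1) / (n_perm + 1))
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c(colnames(S) %||% paste0("axis", seq_len(k)), "r2", "p")
  out <- cbind(variable = variables, out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("envfit_result", "data.frame")
  out
}

# ---------------------------------------------------------------------------

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH adjustment: monotone in the ranked p values, never smaller
#' than the raw p, capped at 1. Input outside `[0, 1]` is an error.
#'
#' @param p Numeric vector of p values.
#' @return Adjusted p values, same order as the input.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bh_fdr <- function(p) {
  .assert(is.numeric(p) && length(p) >= 1, "p must be a numeric vector")
  .assert(all(!is.na(p)) && all(p >= 0 & p <= 1), "p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
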