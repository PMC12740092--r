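# Sample-level PCA and metabolite-level classical (Torgerson) MDS.

new_embedding <- function(ids, coords, variance_explained = NULL,
                          stress = NA_real_) {
  rownames(coords) <- ids
  structure(list(ids = ids, coords = coords,
                 variance_explained = variance_explained, stress = stress),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("embedding: %d items x %d axes\n", nrow(x$coords),
              ncol(x$coords)))
  if (!is.null(x$variance_explained)) {
    cat("  variance explained:",
        paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Principal component analysis of samples
#'
#' Centered (not scaled) PCA; missing cells are imputed by the feature
#' (column) mean first. Components are ordered by decreasing eigenvalue and
#' carry a deterministic sign: the largest-magnitude loading of each
#' component is made positive.
#'
#' @param x numeric matrix, items (samples) in rows, features in columns.
#' @param n_components number of axes to keep (default 2).
#' @return an `embedding` with `variance_explained` per retained axis
#'   (fractions of total variance).
#' @export
pca <- function(x, n_components = 2) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 rows")
  for (j in seq_len(ncol(x))) {
    mj <- mean(x[, j], na.rm = TRUE)
    x[is.na(x[, j]), j] <- mj
  }
  if (all(apply(x, 2, stats::sd) == 0)) stop("constant matrix: PCA undefined")
  fit <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(fit$rotation))
  rot <- fit$rotation[, seq_len(k), drop = FALSE]
  sco <- fit$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(rot[, j]))
    if (rot[i_max, j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  ve <- (fit$sdev^2 / sum(fit$sdev^2))[seq_len(k)]
  ids <- rownames(x)
  if (is.null(ids)) ids <- paste0("item", seq_len(nrow(x)))
  emb <- new_embedding(ids, sco, variance_explained = ve)
  emb$rotation <- rot
  emb
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distance matrix, eigendecomposes, and embeds
#' on the top axes with positive eigenvalues. The reported stress is the
#' normalized residual `sqrt(sum((d_hat - d)^2) / sum(d^2))`.
#'
#' @param d distance matrix (square symmetric or a `dist`).
#' @param n_components number of axes (default 2).
#' @return an `embedding` with `stress` and per-axis eigenvalue fractions.
#' @export
classical_mds <- function(d, n_components = 2) {
  d <- as.matrix(d)
  if (any(!is.finite(d))) stop("distances must be finite")
  n <- nrow(d)
  if (n < 3) stop("need at least 3 items")
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  k <- min(n_components, sum(eig$values > 1e-12))
  coords <- if (k > 0) {
    eig$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(eig$values[seq_len(k)]), k)
  } else {
    matrix(0, n, n_components)
  }
  if (ncol(coords) < n_components) {
    coords <- cbind(coords,
                    matrix(0, n, n_components - ncol(coords)))
  }
  d_hat <- as.matrix(stats::dist(coords))
  stress <- if (sum(d^2) > 0) sqrt(sum((d_hat - d)^2) / sum(d^2)) else 0
  ids <- rownames(d)
  if (is.null(ids)) ids <- paste0("item", seq_len(n))
  pos <- eig$values[eig$values > 1e-12]
  ve <- if (k > 0 && length(pos)) eig$values[seq_len(k)] / sum(pos) else NULL
  new_embedding(ids, coords, variance_explained = ve, stress = stress)
}

#' MDS embedding of metabolites by abundance-profile similarity
#'
#' Metabolites with similar abundance distributions across samples land
#' close together: the dissimilarity is `1 - Pearson r` between log2
#' abundance profiles (pairwise-complete observations), embedded by
#' [classical_mds()].
#'
#' @param table a [feature_table()]
#' @param samples matching [sample_table()]; QC injections are excluded.
#' @param n_components number of axes (default 2).
#' @return an `embedding` of the metabolites.
#' @export
mds_metabolites <- function(table, samples, n_components = 2) {
  check_columns_match(table, samples)
  x <- log2_missing(table$intensities[, !samples$is_qc, drop = FALSE])
  if (nrow(x) < 3) stop("need at least 3 metabolites")
  r <- suppressWarnings(stats::cor(t(x), use = "pairwise.complete.obs"))
  r[is.na(r)] <- 0
  diag(r) <- 1
  d <- 1 - r
  rownames(d) <- colnames(d) <- table$features$feature_id
  classical_mds(d, n_components)
}
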