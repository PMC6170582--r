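#' Principal component analysis of a completed measurement matrix
#'
#' Centred SVD with a deterministic sign convention: within each component
#' the largest-magnitude loading is made positive. Intended for matrices that
#' have already been scaled to unit variance and imputed (no missing cells).
#'
#' @param M Numeric matrix, specimens x codes, no `NA`.
#' @param n_components Number of components to retain (default: all).
#' @return Object of class `pca_result`: `loadings` (codes x components,
#'   orthonormal columns), `scores` (specimens x components) and `explained`
#'   (fraction of total variance per component, non-increasing).
#' @export
pca_morpho <- function(M, n_components = NULL) {
  M <- as.matrix(M)
  if (anyNA(M)) stop("matrix contains missing cells; impute first")
  if (nrow(M) < 2) stop("need at least 2 specimens")
  Mc <- sweep(M, 2, colMeans(M))
  sv <- svd(Mc)
  pos <- sv$d > max(sv$d) * 1e-12
  if (!any(pos)) stop("matrix has rank 0 after centring")
  q <- sum(pos)
  if (!is.null(n_components)) q <- min(q, n_components)
  explained <- sv$d^2 / sum(sv$d^2)
  loadings <- sv$v[, seq_len(q), drop = FALSE]
  scores <- sv$u[, seq_len(q), drop = FALSE] %*% diag(sv$d[seq_len(q)], q)
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(q)) {
    s <- sign(loadings[which.max(abs(loadings[, j])), j])
    if (s < 0) { loadings[, j] <- -loadings[, j]; scores[, j] <- -scores[, j] }
  }
  dimnames(loadings) <- list(colnames(M), paste0("PC", seq_len(q)))
  dimnames(scores) <- list(rownames(M), paste0("PC", seq_len(q)))
  structure(list(loadings = loadings, scores = scores,
                 explained = explained[seq_len(q)], center = colMeans(M)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d components; explained = %s\n",
              ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", ")))
  invisible(x)
}
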