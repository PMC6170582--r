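#' Observed-cell scaling parameters
#'
#' Per-measurement mean and sample standard deviation computed from observed
#' cells only, used to scale measurements to unit variance before imputation
#' and PCA (so that overall size does not dominate purely through the larger
#' absolute spread of the big dimensions).
#'
#' @param x A [specimen_dataset()] or numeric matrix with `NA` for missing.
#' @return List with numeric vectors `mean` and `sd` (named by code) and the
#'   per-column observed counts `n_obs`.
#' @export
fit_scaling <- function(x) {
  M <- as_measurement_matrix(x)
  n_obs <- colSums(!is.na(M))
  if (any(n_obs < 2))
    stop(sprintf("code(s) observed in fewer than 2 specimens: %s",
                 paste(colnames(M)[n_obs < 2], collapse = ", ")))
  mu <- colMeans(M, na.rm = TRUE)
  sd <- apply(M, 2, stats::sd, na.rm = TRUE)
  zero <- sd <= 0 | !is.finite(sd)
  if (any(zero))
    stop(sprintf("zero observed variance in code(s): %s",
                 paste(colnames(M)[zero], collapse = ", ")))
  list(mean = mu, sd = sd, n_obs = n_obs)
}

as_measurement_matrix <- function(x) {
  if (inherits(x, "specimen_dataset")) x$measurements
  else as.matrix(x)
}

# Core iterative-PCA imputer in (already scaled) space.
# Z: matrix with missing entries set to NA. Returns completed Z plus trace.
iterative_pca_core <- function(Z, ncp, mode = c("regularized", "em"),
                               tol = 1e-6, max_iter = 500L) {
  mode <- match.arg(mode)
  n <- nrow(Z); p <- ncol(Z)
  if (ncp < 1 || ncp > min(n, p) - 1)
    stop(sprintf("ncp must lie in [1, %d]", min(n, p) - 1))
  miss <- is.na(Z)
  obj_trace <- numeric(0)
  if (!any(miss)) {
    return(list(completed = Z, iterations = 1L, converged = TRUE,
                obj_trace = obj_trace))
  }
  Z[miss] <- 0  # observed-cell column means are 0 in scaled space
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    mu <- colMeans(Z)
    Zc <- sweep(Z, 2, mu)
    sv <- svd(Zc, nu = ncp, nv = ncp)
    d <- sv$d[seq_len(ncp)]
    if (mode == "regularized") {
      eig <- sv$d^2
      disc <- eig[-seq_len(ncp)]
      sigma2 <- if (length(disc)) mean(disc) else 0
      d <- pmax(d * (d^2 - sigma2) / d^2, 0)
    }
    recon <- sweep(sv$u %*% (d * t(sv$v)), 2, mu, `+`)
    delta <- max(abs(recon[miss] - Z[miss]))
    Z[miss] <- recon[miss]
    obj_trace[iter] <- mean((Z - recon)^2)
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  list(completed = Z, iterations = iter, converged = converged,
       obj_trace = obj_trace)
}

#' Impute missing measurements by iterative PCA (EM)
#'
#' Measurements are scaled to unit variance on observed cells, missing cells
#' are initialized at the column means, and the matrix is repeatedly
#' approximated by a rank-`ncp` truncated SVD whose fitted values replace the
#' missing cells (observed cells are always restored) until the imputed cells
#' change by less than `tol` or `max_iter` is reached. In `"regularized"`
#' mode (the default) the retained singular values are shrunk towards the
#' residual level, `d * (d^2 - sigma2) / d^2` with `sigma2` the mean of the
#' discarded eigenvalues, which curbs EM overfitting when many cells are
#' missing.
#'
#' @param x A [specimen_dataset()] or numeric matrix (`NA` = missing).
#' @param ncp Number of components, in `[1, min(n, p) - 1]`.
#' @param mode `"regularized"` (default) or `"em"` (no shrinkage).
#' @param tol Convergence tolerance on imputed cells, in scaled units.
#' @param max_iter Iteration cap; hitting it flags `converged = FALSE`
#'   without failing.
#' @return Object of class `imputation_result`: `completed` (matrix in mm,
#'   observed cells bit-identical to the input), `imputed_mask` (logical
#'   matrix), `ncp`, `mode`, `iterations`, `converged`, `obj_trace` (mean
#'   squared reconstruction error per iteration) and `cv_errors` (filled by
#'   [select_ncp_cv()], else `NULL`).
#' @export
impute_iterative_pca <- function(x, ncp, mode = c("regularized", "em"),
                                 tol = 1e-6, max_iter = 500L) {
  mode <- match.arg(mode)
  M <- as_measurement_matrix(x)
  sc <- fit_scaling(M)
  Z <- scale_matrix(M, sc)
  core <- iterative_pca_core(Z, ncp, mode, tol, max_iter)
  completed <- unscale_matrix(core$completed, sc)
  miss <- is.na(M)
  completed[!miss] <- M[!miss]  # observed cells exactly preserved
  structure(list(completed = completed, imputed_mask = miss, ncp = as.integer(ncp),
                 mode = mode, iterations = core$iterations,
                 converged = core$converged, obj_trace = core$obj_trace,
                 cv_errors = NULL, scaling = sc),
            class = "imputation_result")
}

scale_matrix <- function(M, sc) sweep(sweep(M, 2, sc$mean), 2, sc$sd, `/`)
unscale_matrix <- function(Z, sc) sweep(sweep(Z, 2, sc$sd, `*`), 2, sc$mean, `+`)

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("imputation_result: %d x %d, %d imputed cells (%.1f%%), ncp = %d (%s), %d iterations, converged = %s\n",
              nrow(x$completed), ncol(x$completed), sum(x$imputed_mask),
              100 * mean(x$imputed_mask), x$ncp, x$mode, x$iterations,
              x$converged))
  invisible(x)
}

#' Select the number of components by fivefold cross-validation
#'
#' Observed cells are randomly partitioned into `folds` groups (seeded); each
#' group is masked in turn, imputed with every candidate rank, and scored by
#' squared error on the held-out cells in scaled space. The candidate with
#' the smallest mean squared error of prediction (MSEP) wins; ties go to the
#' smaller rank. A fold assignment that leaves some column with no observed
#' training cell is resampled (up to 100 attempts).
#'
#' @inheritParams impute_iterative_pca
#' @param candidates Integer vector of ranks to try. Default
#'   `1:min(8, p - 2, n - 2)`.
#' @param folds Number of CV folds (default 5).
#' @param tol,max_iter Inner-imputation settings during CV; looser than the
#'   final imputation defaults because CV only ranks candidates by MSEP.
#' @param seed Integer seed for the fold partition.
#' @return List with `ncp` (selected rank) and `cv_errors` (named numeric
#'   vector of MSEP per candidate).
#' @export
select_ncp_cv <- function(x, candidates = NULL, folds = 5L,
                          mode = c("regularized", "em"), seed = 1L,
                          tol = 1e-4, max_iter = 100L) {
  mode <- match.arg(mode)
  M <- as_measurement_matrix(x)
  n <- nrow(M); p <- ncol(M)
  if (is.null(candidates)) candidates <- seq_len(max(1, min(8, p - 2, n - 2)))
  candidates <- sort(unique(as.integer(candidates)))
  if (!length(candidates)) stop("no candidate ranks")
  if (max(candidates) > min(n, p) - 1) stop("candidate rank out of range")
  sc <- fit_scaling(M)
  Z <- scale_matrix(M, sc)
  obs <- which(!is.na(Z))
  if (length(obs) < folds) stop("not enough observed cells for the requested folds")

  fold_of <- withr::with_seed(seed, {
    for (attempt in 1:100) {
      f <- sample(rep_len(seq_len(folds), length(obs)))
      ok <- TRUE
      for (k in seq_len(folds)) {
        Zk <- Z
        Zk[obs[f == k]] <- NA
        if (any(colSums(!is.na(Zk)) == 0)) { ok <- FALSE; break }
      }
      if (ok) break
      f <- NULL
    }
    if (is.null(f)) stop("could not build folds that keep every column observed")
    f
  })

  err_sum <- stats::setNames(numeric(length(candidates)), candidates)
  n_cells <- 0L
  for (k in seq_len(folds)) {
    held <- obs[fold_of == k]
    Zk <- Z
    Zk[held] <- NA
    n_cells <- n_cells + length(held)
    for (ci in seq_along(candidates)) {
      core <- iterative_pca_core(Zk, candidates[ci], mode, tol, max_iter)
      err_sum[ci] <- err_sum[ci] + sum((core$completed[held] - Z[held])^2)
    }
  }
  msep <- err_sum / n_cells
  best <- candidates[which.min(msep)]  # which.min takes the first = smallest rank
  list(ncp = best, cv_errors = msep)
}

#' Impute with a cross-validated choice of rank
#'
#' Convenience wrapper: runs [select_ncp_cv()] then [impute_iterative_pca()]
#' at the selected rank, recording the CV error map on the result.
#'
#' @inheritParams select_ncp_cv
#' @return An `imputation_result` with `cv_errors` filled in.
#' @export
impute_cv <- function(x, candidates = NULL, folds = 5L,
                      mode = c("regularized", "em"), seed = 1L,
                      tol = 1e-6, max_iter = 500L) {
  mode <- match.arg(mode)
  sel <- select_ncp_cv(x, candidates, folds, mode, seed)
  res <- impute_iterative_pca(x, sel$ncp, mode, tol, max_iter)
  res$cv_errors <- sel$cv_errors
  res
}
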