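#' @name gmm
#' @title Finite Gaussian mixtures over six covariance families
#'
#' @description
#' The clustering core: finite Gaussian mixtures fitted by EM under six
#' covariance parameterizations named by the usual three-letter scheme
#' (volume / shape / orientation):
#'
#' * `EII` spherical, equal volume; `VII` spherical, varying volume;
#' * `EEI` diagonal, equal; `VVI` diagonal, varying;
#' * `EEE` ellipsoidal, shared; `VVV` ellipsoidal, unconstrained.
#'
#' These six realize every structure needed here: equal and unequal variance;
#' spherical, diagonal and ellipsoidal shape; equal and varying volume.
#' Model choice uses BIC in the form `2*loglik - n_params*log(n)`
#' (maximized), so a BIC difference greater than 2 between competing numbers
#' of clusters reads directly as the stability criterion.
NULL

gmm_families <- c("EII", "VII", "EEI", "VVI", "EEE", "VVV")

n_mixture_params <- function(family, K, d) {
  base <- (K - 1L) + K * d
  covp <- switch(family,
    EII = 1L,
    VII = K,
    EEI = d,
    VVI = K * d,
    EEE = d * (d + 1L) / 2L,
    VVV = K * (d * (d + 1L) / 2L))
  base + covp
}

# log density of rows of x under N(mu, Sigma); Sigma d x d
log_dmvnorm <- function(x, mu, Sigma) {
  d <- ncol(x)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) {
    Sigma <- Sigma + diag(1e-6 * mean(diag(Sigma)) + 1e-12, d)
    ch <- chol(Sigma)
  }
  xc <- sweep(x, 2, mu)
  q <- backsolve(ch, t(xc), transpose = TRUE)
  -0.5 * colSums(q^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
}

logsumexp_rows <- function(L) {
  m <- apply(L, 1, max)
  m + log(rowSums(exp(L - m)))
}

# M-step covariance under the family constraint
mstep_cov <- function(x, z, means, family, ridge_kappa = 1e10) {
  n <- nrow(x); d <- ncol(x); K <- ncol(z)
  nk <- colSums(z)
  W <- vector("list", K)
  for (k in seq_len(K)) {
    xc <- sweep(x, 2, means[k, ])
    W[[k]] <- crossprod(xc * z[, k], xc)  # sum_i z_ik (x-mu)(x-mu)'
  }
  Sig <- vector("list", K)
  if (family == "VVV") {
    for (k in seq_len(K)) Sig[[k]] <- W[[k]] / nk[k]
  } else if (family == "EEE") {
    S <- Reduce(`+`, W) / n
    Sig <- rep(list(S), K)
  } else if (family == "VVI") {
    for (k in seq_len(K)) Sig[[k]] <- diag(diag(W[[k]]) / nk[k], d)
  } else if (family == "EEI") {
    dsum <- Reduce(`+`, lapply(W, diag)) / n
    Sig <- rep(list(diag(dsum, d)), K)
  } else if (family == "VII") {
    for (k in seq_len(K)) Sig[[k]] <- diag(rep(sum(diag(W[[k]])) / (d * nk[k]), d), d)
  } else if (family == "EII") {
    s2 <- sum(vapply(W, function(w) sum(diag(w)), 0)) / (d * n)
    Sig <- rep(list(diag(rep(s2, d), d)), K)
  } else stop("unknown family ", family)
  # ridge near-singular covariances
  for (k in seq_len(K)) {
    S <- Sig[[k]]
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0 || max(ev) / max(min(ev), 1e-300) > ridge_kappa)
      Sig[[k]] <- S + diag(1e-6 * mean(diag(S)) + 1e-12, d)
  }
  Sig
}

em_once <- function(x, K, family, z0, tol, max_iter) {
  n <- nrow(x); d <- ncol(x)
  z <- z0
  loglik_trace <- numeric(0)
  loglik <- -Inf
  means <- NULL; Sig <- NULL; w <- NULL
  for (iter in seq_len(max_iter)) {
    nk <- colSums(z)
    if (any(nk < 1e-6)) return(list(failed = TRUE, reason = "empty component"))
    w <- nk / n
    means <- (t(z) %*% x) / nk
    Sig <- mstep_cov(x, z, means, family)
    L <- matrix(0, n, K)
    for (k in seq_len(K))
      L[, k] <- log(w[k]) + log_dmvnorm(x, means[k, ], Sig[[k]])
    lse <- logsumexp_rows(L)
    new_loglik <- sum(lse)
    z <- exp(L - lse)
    loglik_trace <- c(loglik_trace, new_loglik)
    if (is.finite(loglik) && abs(new_loglik - loglik) < tol * (1 + abs(new_loglik))) {
      loglik <- new_loglik
      break
    }
    loglik <- new_loglik
  }
  list(failed = FALSE, weights = w, means = means, covariances = Sig,
       loglik = loglik, z = z, loglik_trace = loglik_trace,
       iterations = length(loglik_trace))
}

hard_to_soft <- function(labels, K) {
  n <- length(labels)
  z <- matrix(0, n, K)
  z[cbind(seq_len(n), labels)] <- 1
  z
}

#' Fit a Gaussian mixture with a constrained covariance family
#'
#' EM with the family's covariance structure re-imposed at every M-step.
#' Initialization is Ward agglomerative clustering cut at `K`
#' (`"hierarchical"`, the default — the behaviour of the field's standard
#' model-based clustering tools) or random hard assignments; `n_restarts > 1`
#' adds random restarts and the best start by log-likelihood wins.
#' Near-singular component covariances get a small ridge
#' (`1e-6 * mean(diag)`) when their condition number exceeds `1e10`. A
#' restart whose EM empties a component is retried with a perturbed start (up
#' to 5 times) before being dropped.
#'
#' @param x Numeric matrix (specimens x dimensions), e.g. PCA scores.
#' @param K Number of components (`1 <= K < n`).
#' @param family One of `"EII"`, `"VII"`, `"EEI"`, `"VVI"`, `"EEE"`, `"VVV"`.
#' @param init `"hierarchical"` or `"random"`.
#' @param n_restarts Total number of starts (default 1: hierarchical only).
#' @param seed Integer seed for the random restarts.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap.
#' @return Object of class `mixture_model`: `family`, `K`, `weights`, `means`
#'   (K x d), `covariances` (list of d x d), `loglik`, `bic`, `n_params`,
#'   `loglik_trace`, `d`, `n`.
#' @export
fit_gmm <- function(x, K, family = "VVV", init = c("hierarchical", "random"),
                    n_restarts = 1L, seed = 1L, tol = 1e-8, max_iter = 500L) {
  x <- as.matrix(x)
  init <- match.arg(init)
  family <- match.arg(family, gmm_families)
  n <- nrow(x); d <- ncol(x)
  if (K < 1 || K >= n) stop("need 1 <= K < n")

  starts <- list()
  if (init == "hierarchical") {
    # Ward tree on standardized columns: the agglomeration should not be
    # dominated by the highest-variance axis, only by cluster geometry
    xs <- scale(x)
    xs[, attr(xs, "scaled:scale") == 0] <- 0
    hc <- stats::hclust(stats::dist(xs), method = "ward.D2")
    starts[[1]] <- hard_to_soft(stats::cutree(hc, k = K), K)
  }
  withr::with_seed(seed, {
    while (length(starts) < n_restarts) {
      lab <- sample(rep_len(seq_len(K), n))
      starts[[length(starts) + 1]] <- hard_to_soft(lab, K)
    }
    best <- NULL
    for (z0 in starts) {
      fit <- em_once(x, K, family, z0, tol, max_iter)
      retry <- 0
      while (isTRUE(fit$failed) && retry < 5) {
        retry <- retry + 1
        lab <- sample(rep_len(seq_len(K), n))
        fit <- em_once(x, K, family, hard_to_soft(lab, K), tol, max_iter)
      }
      if (isTRUE(fit$failed)) next
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    if (is.null(best)) stop("all EM starts failed (empty components)")
    np <- n_mixture_params(family, K, d)
    structure(list(family = family, K = as.integer(K), weights = best$weights,
                   means = best$means, covariances = best$covariances,
                   loglik = best$loglik, n_params = np,
                   bic = 2 * best$loglik - np * log(n),
                   loglik_trace = best$loglik_trace, d = d, n = n),
              class = "mixture_model")
  })
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("mixture_model: %s, K = %d (d = %d, n = %d), loglik = %.3f, BIC = %.3f\n",
              x$family, x$K, x$d, x$n, x$loglik, x$bic))
  invisible(x)
}

#' Posterior classification under a fitted mixture
#'
#' Responsibilities by Bayes' rule; `label` is the maximum a posteriori
#' component and `uncertainty = 1 - max posterior` (in `[0, 1 - 1/K]`).
#'
#' @param model A `mixture_model`.
#' @param x Matrix with the dimensionality the model was fitted on.
#' @return Object of class `gmm_assignment`: `z` (n x K responsibilities,
#'   rows sum to 1), `labels`, `uncertainty`.
#' @export
classify <- function(model, x) {
  stopifnot(inherits(model, "mixture_model"))
  x <- as.matrix(x)
  if (ncol(x) != model$d) stop("dimension mismatch: model fitted on d = ", model$d)
  n <- nrow(x)
  L <- matrix(0, n, model$K)
  for (k in seq_len(model$K))
    L[, k] <- log(model$weights[k]) +
      log_dmvnorm(x, model$means[k, ], model$covariances[[k]])
  lse <- logsumexp_rows(L)
  z <- exp(L - lse)
  labels <- max.col(z, ties.method = "first")
  structure(list(z = z, labels = labels, uncertainty = 1 - apply(z, 1, max),
                 K = model$K),
            class = "gmm_assignment")
}

#' Select a mixture model over a grid of K and families by BIC
#'
#' Fits every (K, family) pair, keeps the best by BIC (ties: smaller K, then
#' fewer parameters), and reports stability: the result is stable when the
#' best BIC exceeds the best BIC achieved at any *different* K by more than
#' `stability_delta` (default 2).
#'
#' @inheritParams fit_gmm
#' @param K_range Integer vector of cluster numbers to try.
#' @param families Character vector of covariance families.
#' @param stability_delta BIC margin over competing K defining stability.
#' @return List with `model` (best `mixture_model`), `bic_table` (data frame
#'   K x family x BIC), `stable` (logical) and `delta_bic` (margin over the
#'   best different-K competitor).
#' @export
select_model <- function(x, K_range = 1:6, families = gmm_families,
                         stability_delta = 2, init = "hierarchical",
                         n_restarts = 1L, seed = 1L, tol = 1e-8,
                         max_iter = 500L) {
  x <- as.matrix(x)
  families <- match.arg(families, gmm_families, several.ok = TRUE)
  rows <- list()
  fits <- list()
  for (K in K_range) {
    for (fam in families) {
      fit <- tryCatch(
        fit_gmm(x, K, fam, init = init, n_restarts = n_restarts,
                seed = seed + K, tol = tol, max_iter = max_iter),
        error = function(e) NULL)
      rows[[length(rows) + 1]] <- data.frame(
        K = K, family = fam,
        loglik = if (is.null(fit)) NA_real_ else fit$loglik,
        n_params = if (is.null(fit)) NA_integer_ else fit$n_params,
        bic = if (is.null(fit)) NA_real_ else fit$bic)
      if (!is.null(fit)) fits[[paste(K, fam)]] <- fit
    }
  }
  tab <- do.call(rbind, rows)
  if (!length(fits)) stop("all mixture fits failed")
  ok <- !is.na(tab$bic)
  # best by BIC; ties to smaller K then fewer parameters
  ord <- order(-tab$bic, tab$K, tab$n_params, na.last = TRUE)
  best_row <- tab[ord[1], ]
  best <- fits[[paste(best_row$K, best_row$family)]]
  other <- tab$bic[ok & tab$K != best_row$K]
  delta <- if (length(other)) best_row$bic - max(other) else Inf
  list(model = best, bic_table = tab, stable = delta > stability_delta,
       delta_bic = delta)
}

#' Stepped inclusion of principal components
#'
#' Principal components are introduced one at a time: [select_model()] is run
#' on the first m score columns for m = 1, 2, ... until BIC identifies a
#' distinct stable pattern (margin > `stability_delta` over competing cluster
#' numbers, with K > 1 — a stable single-component fit is no pattern and the
#' stepping continues). The first such m wins; if no m qualifies the best
#' overall fit is returned flagged unstable.
#'
#' @inheritParams select_model
#' @param pca A `pca_result` (or matrix of scores).
#' @param max_pcs Maximum number of components to include.
#' @return List: `n_pcs_used`, `model`, `stable`, `bic_table`, `delta_bic`,
#'   plus `per_m` (the selection at each m tried).
#' @export
stepped_pc_selection <- function(pca, K_range = 1:6, families = gmm_families,
                                 max_pcs = 4L, stability_delta = 2,
                                 init = "hierarchical", n_restarts = 1L,
                                 seed = 1L, tol = 1e-8, max_iter = 500L) {
  scores <- if (inherits(pca, "pca_result")) pca$scores else as.matrix(pca)
  max_pcs <- min(max_pcs, ncol(scores))
  per_m <- list()
  for (m in seq_len(max_pcs)) {
    sel <- select_model(scores[, seq_len(m), drop = FALSE], K_range, families,
                        stability_delta, init, n_restarts, seed, tol, max_iter)
    per_m[[m]] <- sel
    if (sel$stable && sel$model$K > 1)
      return(list(n_pcs_used = m, model = sel$model, stable = TRUE,
                  bic_table = sel$bic_table, delta_bic = sel$delta_bic,
                  per_m = per_m))
  }
  # never stable: best overall by BIC across the m tried
  bics <- vapply(per_m, function(s) s$model$bic, 0)
  m <- which.max(bics)
  list(n_pcs_used = m, model = per_m[[m]]$model, stable = FALSE,
       bic_table = per_m[[m]]$bic_table, delta_bic = per_m[[m]]$delta_bic,
       per_m = per_m)
}
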