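test_that("scaling parameters come from observed cells only", {
  M <- cbind(F1 = c(10, 20, 30), F2 = c(10, NA, 30), F3 = c(1, 2, 4))
  sc <- fit_scaling(M)
  expect_equal(unname(sc$mean["F1"]), 20)
  expect_equal(unname(sc$sd["F1"]), 10)   # sample sd, n - 1
  expect_equal(unname(sc$mean["F2"]), 20) # masked cell excluded
  expect_equal(unname(sc$n_obs["F2"]), 2)
  expect_error(fit_scaling(cbind(F1 = c(5, 5, 5))), "F1")
  expect_error(fit_scaling(cbind(F1 = c(5, NA, NA))), "fewer than 2")
})

test_that("a complete matrix passes through unchanged in one iteration", {
  X <- rank_k_matrix(10, 6, 3, noise = 1, seed = 2)
  res <- impute_iterative_pca(X, ncp = 2)
  expect_identical(res$completed, X)
  expect_equal(res$iterations, 1L)
  expect_true(res$converged)
  expect_equal(sum(res$imputed_mask), 0)
})

test_that("observed cells are never modified", {
  for (s in 1:5) {
    X <- rank_k_matrix(15, 8, 2, noise = 0.5, seed = s)
    mask <- withr::with_seed(s, matrix(stats::runif(120) < 0.15, 15, 8))
    mask[rowSums(!mask) == 0, 1] <- FALSE
    Xm <- X; Xm[mask] <- NA
    for (mode in c("em", "regularized")) {
      res <- impute_iterative_pca(Xm, ncp = 2, mode = mode)
      expect_identical(res$completed[!mask], X[!mask])
      expect_identical(res$imputed_mask, is.na(Xm))
    }
  }
})

test_that("an exact rank-1 structure recovers a masked cell", {
  v <- c(2, 5, 9, 14, 20)
  cvec <- c(1, 1.2, 1.5, 1.9, 2.4, 3.0)
  X <- outer(cvec, v)
  colnames(X) <- paste0("F", 1:5)
  Xm <- X; Xm[3, 4] <- NA
  res <- impute_iterative_pca(Xm, ncp = 1, mode = "em", tol = 1e-10)
  expect_equal(res$completed[3, 4], X[3, 4], tolerance = 1e-6)
  expect_true(res$converged)
})

test_that("two perfectly correlated columns impute by the linear relation", {
  x <- c(10, 14, 19, 25, 31, 40)
  y <- 3 + 2.5 * x
  X <- cbind(F1 = x, F2 = y)
  Xm <- X; Xm[5, 2] <- NA
  res <- impute_iterative_pca(Xm, ncp = 1, mode = "em", tol = 1e-12,
                              max_iter = 2000)
  # oracle: the regression of the observed pairs, fitted independently
  fit <- stats::lm(y ~ x, data = data.frame(x = x[-5], y = y[-5]))
  oracle <- unname(stats::predict(fit, data.frame(x = x[5])))
  expect_equal(unname(res$completed[5, 2]), oracle, tolerance = 1e-6)
})

test_that("the EM objective is non-increasing across iterations", {
  for (s in 1:3) {
    X <- rank_k_matrix(20, 8, 3, noise = 1, seed = s + 10)
    mask <- withr::with_seed(s, matrix(stats::runif(160) < 0.2, 20, 8))
    mask[rowSums(!mask) == 0, 1] <- FALSE
    Xm <- X; Xm[mask] <- NA
    res <- impute_iterative_pca(Xm, ncp = 3, mode = "em")
    tr <- res$obj_trace
    expect_true(all(diff(tr) <= 1e-12 * (1 + abs(tr[-length(tr)]))))
  }
})

test_that("non-convergence at max_iter is flagged, not fatal", {
  X <- rank_k_matrix(20, 8, 3, noise = 2, seed = 3)
  mask <- withr::with_seed(4, matrix(stats::runif(160) < 0.3, 20, 8))
  mask[rowSums(!mask) == 0, 1] <- FALSE
  Xm <- X; Xm[mask] <- NA
  res <- impute_iterative_pca(Xm, ncp = 3, tol = 1e-14, max_iter = 3L)
  expect_false(res$converged)
  expect_equal(res$iterations, 3L)
})

test_that("ncp outside the valid range errors", {
  X <- rank_k_matrix(6, 4, 2, seed = 5)
  X[2, 3] <- NA
  expect_error(impute_iterative_pca(X, ncp = 0), "ncp")
  expect_error(impute_iterative_pca(X, ncp = 4), "ncp")
})

test_that("cross-validation selects the true rank on low-rank data", {
  X <- rank_k_matrix(40, 8, 2, noise = 0.3, seed = 7)
  mask <- withr::with_seed(7, matrix(stats::runif(320) < 0.1, 40, 8))
  mask[rowSums(!mask) == 0, 1] <- FALSE
  Xm <- X; Xm[mask] <- NA
  sel <- select_ncp_cv(Xm, candidates = 1:4, seed = 7)
  expect_equal(sel$ncp, 2)
  expect_length(sel$cv_errors, 4)
  expect_true(all(is.finite(sel$cv_errors)))
})

test_that("cross-validation picks the smallest rank on structureless noise", {
  X <- withr::with_seed(21, matrix(stats::rnorm(40 * 8, 100, 5), 40, 8,
                                   dimnames = list(NULL, paste0("F", 1:8))))
  Xm <- X
  mask <- withr::with_seed(22, matrix(stats::runif(320) < 0.1, 40, 8))
  mask[rowSums(!mask) == 0, 1] <- FALSE
  Xm[mask] <- NA
  sel <- select_ncp_cv(Xm, candidates = 1:4, seed = 23)
  expect_equal(sel$ncp, 1)
})

test_that("impute_cv records the CV error map on the result", {
  g <- generate_specimens(generator_config("femur", n_per_cluster = 10, seed = 31))
  res <- impute_cv(g$dataset$measurements, seed = 31)
  expect_false(is.null(res$cv_errors))
  expect_equal(unname(res$ncp),
               as.integer(names(res$cv_errors)[which.min(res$cv_errors)]))
})
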