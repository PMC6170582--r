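test_that("PCA on collinear points loads everything on one component", {
  x <- seq(-3, 3, length.out = 20)
  M <- cbind(a = x, b = 2 * x + 5)
  pc <- pca_morpho(M)
  # the zero-variance direction is dropped: one component explains everything
  expect_equal(pc$explained[1], 1, tolerance = 1e-12)
  expect_equal(ncol(pc$scores), 1)
})

test_that("PCA explained fractions are about equal on an isotropic cloud", {
  X <- withr::with_seed(5, matrix(stats::rnorm(4000 * 3), 4000, 3))
  pc <- pca_morpho(X)
  expect_true(all(abs(pc$explained - 1 / 3) < 0.03))
  expect_true(all(diff(pc$explained) <= 1e-12))
})

test_that("PCA matches the reference implementation up to sign on a fixture", {
  M <- matrix(c(2.1, 3.3, 0.5, 4.2,
                1.9, 2.8, 1.1, 3.9,
                3.3, 4.1, 0.2, 5.0,
                2.7, 3.0, 0.9, 4.4,
                1.2, 2.2, 1.4, 3.1), 5, 4, byrow = TRUE)
  pc <- pca_morpho(M)
  ref <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  q <- ncol(pc$scores)
  for (j in seq_len(q)) {
    s <- sign(sum(pc$loadings[, j] * ref$rotation[, j]))
    expect_equal(pc$loadings[, j], s * unname(ref$rotation[, j]), tolerance = 1e-8)
    expect_equal(unname(pc$scores[, j]), s * unname(ref$x[, j]), tolerance = 1e-8)
  }
  expect_equal(pc$explained[seq_len(q)],
               (ref$sdev^2 / sum(ref$sdev^2))[seq_len(q)], tolerance = 1e-12)
  # orthonormal loadings
  expect_equal(unname(crossprod(pc$loadings)), diag(q), tolerance = 1e-10)
  expect_error(pca_morpho(matrix(1, 3, 2)), "rank 0")
})

test_that("two tight 1-D clusters are recovered with negligible uncertainty", {
  b <- gaussian_blobs(matrix(c(0, 10), 2, 1), n_each = 25, sd = 0.1, seed = 3)
  for (fam in c("EII", "VVV")) {
    fit <- fit_gmm(b$x, K = 2, family = fam, seed = 3)
    expect_equal(sort(as.numeric(fit$means)), c(0, 10), tolerance = 0.1)
    asn <- classify(fit, b$x)
    expect_true(all(asn$uncertainty < 1e-6))
    expect_equal(rowSums(asn$z), rep(1, 50), tolerance = 1e-12)
  }
})

test_that("K = 1 reproduces the closed-form Gaussian MLE log-likelihood", {
  x <- withr::with_seed(8, matrix(stats::rnorm(40, 5, 2), 40, 1))
  fit <- fit_gmm(x, K = 1, family = "VVV", seed = 8)
  mu <- mean(x); s2 <- mean((x - mu)^2)  # MLE variance (divisor n)
  ll <- sum(stats::dnorm(x, mu, sqrt(s2), log = TRUE))
  expect_equal(fit$loglik, ll, tolerance = 1e-8)
  expect_equal(fit$n_params, 2L)
})

test_that("a shared spherical covariance is recovered within 10%", {
  b <- gaussian_blobs(rbind(c(0, 0), c(8, 8)), n_each = 250, sd = 1.5, seed = 9)
  fit <- fit_gmm(b$x, K = 2, family = "EII", seed = 9)
  expect_equal(fit$covariances[[1]][1, 1], 1.5^2, tolerance = 0.1)
  expect_identical(fit$covariances[[1]], fit$covariances[[2]])
})

test_that("EM log-likelihood is non-decreasing along the trace", {
  b <- gaussian_blobs(rbind(c(0, 0), c(4, 1), c(-3, 5)), n_each = 30,
                      sd = 1, seed = 12)
  for (fam in c("EII", "VVI", "VVV")) {
    fit <- fit_gmm(b$x, K = 3, family = fam, seed = 12)
    tr <- fit$loglik_trace
    expect_true(all(diff(tr) >= -1e-9 * (1 + abs(tr[-length(tr)]))))
  }
})

test_that("nested families order their maximized log-likelihoods", {
  b <- gaussian_blobs(rbind(c(0, 0), c(5, 3)), n_each = 40, sd = 1, seed = 14)
  ll <- vapply(c("EII", "EEE", "VVV"), function(f)
    fit_gmm(b$x, K = 2, family = f, seed = 14)$loglik, 0)
  expect_true(ll["VVV"] >= ll["EEE"] - 1e-6)
  expect_true(ll["EEE"] >= ll["EII"] - 1e-6)
})

test_that("EM reaches at least the best hard partition on tiny 1-D data", {
  x <- withr::with_seed(17, c(stats::rnorm(4, 0, 0.6), stats::rnorm(4, 4, 0.6)))
  fit <- fit_gmm(matrix(x, 8, 1), K = 2, family = "VII", seed = 17,
                 n_restarts = 5)
  # brute force: every 2-block partition with >= 2 points per block, scored as
  # the mixture log-likelihood of its hard-assignment parameter estimates
  best <- -Inf
  for (bits in 0:(2^8 - 1)) {
    grp <- as.logical(bitwAnd(bits, 2^(0:7)))
    if (sum(grp) < 2 || sum(!grp) < 2) next
    w <- c(mean(grp), mean(!grp))
    mu <- c(mean(x[grp]), mean(x[!grp]))
    s2 <- c(mean((x[grp] - mu[1])^2), mean((x[!grp] - mu[2])^2))
    if (any(s2 <= 0)) next
    ll <- sum(log(w[1] * stats::dnorm(x, mu[1], sqrt(s2[1])) +
                  w[2] * stats::dnorm(x, mu[2], sqrt(s2[2]))))
    best <- max(best, ll)
  }
  expect_gte(fit$loglik, best - 1e-6)
})

test_that("our fits agree with the reference mixture implementation", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))  # Mclust evaluates helpers in the caller
  b <- gaussian_blobs(rbind(c(0, 0), c(6, 4), c(-5, 6)), n_each = 40,
                      sd = 1, seed = 20)
  for (fam in c("EII", "EEE", "VVV")) {
    ours <- fit_gmm(b$x, K = 3, family = fam, seed = 20)
    ref <- mclust::Mclust(b$x, G = 3, modelNames = fam, verbose = FALSE)
    expect_equal(ours$loglik, ref$loglik, tolerance = 1e-4)
    # BIC agreement implies the parameter counts agree too
    expect_equal(ours$bic, as.numeric(ref$bic), tolerance = 1e-3)
    expect_equal(ours$bic, 2 * ours$loglik - ours$n_params * log(ours$n))
  }
})

test_that("model selection finds the generating K and flags stability", {
  b <- gaussian_blobs(rbind(c(0, 0), c(10, 0), c(5, 9)), n_each = 40,
                      sd = 1, seed = 22)
  sel <- select_model(b$x, K_range = 1:5, seed = 22)
  expect_equal(sel$model$K, 3)
  expect_true(sel$stable)
  expect_equal(nrow(sel$bic_table), 5 * 6)
  # single Gaussian cloud
  x1 <- withr::with_seed(23, matrix(stats::rnorm(200), 100, 2))
  sel1 <- select_model(x1, K_range = 1:4, seed = 23)
  expect_equal(sel1$model$K, 1)
})

test_that("classification uncertainty behaves at the component mean and midpoint", {
  fit <- fit_gmm(gaussian_blobs(matrix(c(0, 10), 2, 1), 25, sd = 1, seed = 5)$x,
                 K = 2, family = "EII", seed = 5)
  at_mean <- classify(fit, matrix(fit$means[1, ], 1, 1))
  expect_lt(at_mean$uncertainty, 1e-4)
  midpoint <- matrix(mean(fit$means), 1, 1)
  at_mid <- classify(fit, midpoint)
  expect_equal(at_mid$uncertainty, 0.5, tolerance = 0.02)
  expect_error(classify(fit, matrix(0, 1, 2)), "dimension mismatch")
})

test_that("stepped inclusion finds structure hidden beyond the first component", {
  # separation only on the second dimension; first is pure noise with the
  # larger variance, so it becomes PC1
  withr::with_seed(30, {
    x1 <- stats::rnorm(160, 0, 10)
    x2 <- c(stats::rnorm(80, 0, 1), stats::rnorm(80, 8, 1))
  })
  pc <- pca_morpho(cbind(x1, x2))
  st <- stepped_pc_selection(pc, K_range = 1:4, max_pcs = 3, seed = 30)
  expect_equal(st$n_pcs_used, 2)
  expect_equal(st$model$K, 2)
  expect_true(st$stable)
  # clusters separated on PC1 need only one component
  b <- gaussian_blobs(matrix(c(0, 20), 2, 1), n_each = 40, sd = 1, seed = 31)
  pc1 <- pca_morpho(cbind(b$x, withr::with_seed(31, stats::rnorm(80, 0, 0.5))))
  st1 <- stepped_pc_selection(pc1, K_range = 1:4, max_pcs = 3, seed = 31)
  expect_equal(st1$n_pcs_used, 1)
  expect_equal(st1$model$K, 2)
  # structureless data come back flagged unstable
  xn <- withr::with_seed(32, matrix(stats::rnorm(120), 60, 2))
  stn <- stepped_pc_selection(pca_morpho(xn), K_range = 1:4, max_pcs = 2, seed = 32)
  expect_false(stn$stable)
})
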