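# Small in-code fixtures shared across test files.

# A tiny complete femur table (3 specimens x 20 codes) written to a temp CSV.
tiny_femur_csv <- function(path = tempfile(fileext = ".csv"), holes = FALSE) {
  codes <- scheme_codes("femur")
  base <- seq(10, 200, length.out = length(codes))
  M <- rbind(base, base * 1.1, base * 1.25)
  colnames(M) <- codes
  df <- data.frame(specimen_id = c("a", "b", "c"),
                   collection = "TEST", locality = c("north", NA, "south"))
  df <- cbind(df, as.data.frame(M))
  if (holes) df[2, codes[1:5]] <- NA
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# Low-rank matrix with named columns, for imputation oracles.
rank_k_matrix <- function(n, p, k, noise = 0, seed = 1) {
  withr::with_seed(seed, {
    U <- matrix(stats::rnorm(n * k), n, k)
    V <- matrix(stats::rnorm(p * k), p, k)
    X <- 100 + 10 * (U %*% t(V)) + matrix(stats::rnorm(n * p, 0, noise), n, p)
    colnames(X) <- paste0("F", seq_len(p))
    X
  })
}

# Gaussian blobs in d dimensions at given centres.
gaussian_blobs <- function(centres, n_each, sd = 1, seed = 1) {
  centres <- as.matrix(centres)
  withr::with_seed(seed, {
    X <- do.call(rbind, lapply(seq_len(nrow(centres)), function(k)
      matrix(stats::rnorm(n_each * ncol(centres), 0, sd), n_each) +
        matrix(centres[k, ], n_each, ncol(centres), byrow = TRUE)))
    list(x = X, labels = rep(seq_len(nrow(centres)), each = n_each))
  })
}
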