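# Fixture builders and independent oracles shared across the suite.

# Tiny gmv_matrix with p masked voxels on a 4x4x4 grid (p <= 64), log-normal
# positive values.
small_gmv <- function(n = 6, p = 10, seed = 1, sd_log = 0.3) {
  set.seed(seed)
  mask <- array(FALSE, dim = c(4, 4, 4))
  mask[seq_len(p)] <- TRUE
  data <- exp(matrix(rnorm(n * p, log(0.5), sd_log), n, p))
  gmv_matrix(data, sprintf("S%02d", seq_len(n)), mask)
}

# Independent OLS by explicit normal equations (never QR), for cross-checks.
oracle_ols <- function(X, y) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fitted <- as.numeric(X %*% beta)
  list(beta = as.numeric(beta), fitted = fitted,
       rss = sum((y - fitted)^2))
}

# Independent nested-model F test from two normal-equation fits.
oracle_f_test <- function(X0, X1, y) {
  f0 <- oracle_ols(X0, y); f1 <- oracle_ols(X1, y)
  df1 <- ncol(X1) - ncol(X0)
  df2 <- length(y) - ncol(X1)
  f <- ((f0$rss - f1$rss) / df1) / (f1$rss / df2)
  list(f = f, df1 = df1, df2 = df2, p = pf(f, df1, df2, lower.tail = FALSE))
}

# Independent exhaustive AIC subset search over SSF columns (+ intercept and
# TIV), enumerated with its own loop order and normal-equation fits.
oracle_select <- function(ssf, y, tiv, k_max, max_subset) {
  n <- length(y)
  best <- NULL
  for (size in seq_len(max_subset)) {
    for (S in utils::combn(k_max, size, simplify = FALSE)) {
      X <- cbind(1, ssf[, S, drop = FALSE], tiv)
      rss <- oracle_ols(X, y)$rss
      k <- size + 1
      aic <- if (rss <= 1e-12 * max(sum((y - mean(y))^2), 1)) -Inf
             else n * log(rss / n) + 2 * (k + 1)
      if (is.null(best) || aic < best$aic - 1e-9)
        best <- list(S = S, aic = aic)
    }
  }
  best
}

# Independent PCA oracle: eigendecomposition of the voxel covariance matrix
# (p x p), usable for small fixtures only.
oracle_pca <- function(centered) {
  G <- t(centered) %*% centered          # p x p cross-product
  e <- eigen(G, symmetric = TRUE)
  K <- min(nrow(centered) - 1, ncol(centered))
  list(loadings = t(e$vectors[, seq_len(K), drop = FALSE]),
       eigenvalues = e$values[seq_len(K)])
}

# Small cohort config used across tests (about 150 voxels, fast).
small_cohort_config <- function(seed, n_subjects = 40, ...) {
  synthetic_config(n_subjects = n_subjects, grid_shape = c(8L, 8L, 8L),
                   mask_fraction = 0.3, seed = seed, ...)
}
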