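#' Voxelwise log transform of a GMV matrix
#'
#' First step of the Scaled Subprofile Model: elementwise natural logarithm
#' of the masked gray matter values.  Under the `"strict"` policy any value
#' <= 0 is an error; under `"epsilon"` a small offset is added first, since
#' modulated VBM maps can contain exact zeros at tissue edges.
#'
#' @param gmv a [gmv_matrix] or a plain numeric matrix (subjects x voxels).
#' @param offset_policy `"strict"` (default) or `"epsilon"`.
#' @param epsilon offset used under the epsilon policy; default is 1e-6 of
#'   the median masked value.
#' @return Numeric matrix of the same shape, `log(x)` (or `log(x + epsilon)`).
#' @export
log_transform <- function(gmv, offset_policy = c("strict", "epsilon"),
                          epsilon = NULL) {
  offset_policy <- match.arg(offset_policy)
  x <- if (inherits(gmv, "gmv_matrix")) gmv$data else as.matrix(gmv)
  if (offset_policy == "strict") {
    if (any(x <= 0)) {
      bad <- which(x <= 0, arr.ind = TRUE)[1, ]
      stop(sprintf(
        "non-positive value at subject %d, voxel %d under strict policy",
        bad[1], bad[2]))
    }
    log(x)
  } else {
    if (is.null(epsilon)) epsilon <- 1e-6 * stats::median(x)
    if (any(x + epsilon <= 0))
      stop("values remain non-positive after epsilon offset")
    log(x + epsilon)
  }
}

#' Double-center a subjects-by-voxels matrix
#'
#' Subtracts the mean across voxels (each subject's global level) and the
#' mean across subjects (the group mean voxel profile) at each voxel, adding
#' back the grand mean:
#' `centered[s, v] = x[s, v] - row_mean[s] - col_mean[v] + grand_mean`.
#' The result has all row and column means zero; the returned means are
#' those of the input.
#'
#' @param x finite numeric matrix with at least 2 rows and 2 columns.
#' @return List with `centered`, `row_means`, `col_means`, `grand_mean`.
#' @export
double_center <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("double centering needs at least 2 rows and 2 columns")
  if (!all(is.finite(x))) stop("non-finite values in input")
  rm <- rowMeans(x)
  cm <- colMeans(x)
  gm <- mean(x)
  centered <- x - rm
  centered <- sweep(centered, 2L, cm) + gm
  list(centered = centered, row_means = rm, col_means = cm, grand_mean = gm)
}

#' Principal component decomposition of double-centered SSM data
#'
#' Thin singular value decomposition of the double-centered log-GMV matrix,
#' retaining `K = min(n_subjects - 1, n_voxels)` components.  Component voxel
#' loadings are the unit-norm right singular vectors; subject score factors
#' (SSF) are the left singular vectors scaled by the singular values, so that
#' `centered = ssf %*% loadings` exactly at full rank.  Eigenvalues are the
#' squared singular values and `var_fraction` their share of total variance.
#'
#' A deterministic sign convention is applied: within each loading the
#' element of largest magnitude is made positive (PCA signs are otherwise
#' arbitrary, which would break reproducibility and bootstrap alignment).
#'
#' @param centered double-centered matrix (checked: row/column means must
#'   vanish to `center_tol` relative to the matrix scale).
#' @param center_tol tolerance for the centering check (default 1e-8).
#' @return Object of class `"ssm_decomposition"`: list with `loadings`
#'   (K x n_voxels), `ssf` (n_subjects x K), `eigenvalues`, `var_fraction`,
#'   `centered`, `row_means`, `col_means`, `grand_mean`, `n_subjects`,
#'   `n_voxels`.  The means slots are `NULL` unless supplied via `centering`.
#' @param centering optional list from [double_center()] whose means are
#'   carried along for prospective scoring of new subjects.
#' @export
ssm_pca <- function(centered, centering = NULL, center_tol = 1e-8) {
  centered <- as.matrix(centered)
  n <- nrow(centered); p <- ncol(centered)
  scale_ref <- max(1, max(abs(centered)))
  if (max(abs(rowMeans(centered))) > center_tol * scale_ref ||
      max(abs(colMeans(centered))) > center_tol * scale_ref)
    stop("input is not double-centered; run double_center() first")
  K <- min(n - 1L, p)
  s <- svd(centered, nu = K, nv = K)
  d <- s$d[seq_len(K)]
  loadings <- t(s$v)              # K x p, rows unit norm
  ssf <- s$u %*% diag(d, K, K)    # n x K, component scores
  # sign convention: largest-magnitude element of each loading positive
  for (k in seq_len(K)) {
    j <- which.max(abs(loadings[k, ]))
    if (loadings[k, j] < 0) {
      loadings[k, ] <- -loadings[k, ]
      ssf[, k] <- -ssf[, k]
    }
  }
  ev <- s$d^2
  structure(
    list(loadings = loadings, ssf = ssf,
         eigenvalues = ev[seq_len(K)],
         var_fraction = ev[seq_len(K)] / sum(ev),
         centered = centered,
         row_means = centering$row_means,
         col_means = centering$col_means,
         grand_mean = centering$grand_mean,
         n_subjects = n, n_voxels = p),
    class = "ssm_decomposition")
}

#' @export
print.ssm_decomposition <- function(x, ...) {
  K <- length(x$eigenvalues)
  cat("SSM decomposition:", x$n_subjects, "subjects x", x$n_voxels,
      "voxels,", K, "components\n")
  kk <- seq_len(min(6L, K))
  cat("Variance fractions:",
      paste(sprintf("PC%d %.1f%%", kk, 100 * x$var_fraction[kk]),
            collapse = ", "),
      if (K > 6L) "...", "\n")
  invisible(x)
}

#' Decompose a GMV dataset with the Scaled Subprofile Model
#'
#' Convenience wrapper chaining [log_transform()], [double_center()] and
#' [ssm_pca()].
#'
#' @inheritParams log_transform
#' @inheritParams ssm_pca
#' @return An `"ssm_decomposition"` carrying the centering means, so new
#'   subjects can be projected later.
#' @export
ssm_decompose <- function(gmv, offset_policy = "strict", epsilon = NULL,
                          center_tol = 1e-8) {
  lx <- log_transform(gmv, offset_policy, epsilon)
  ctr <- double_center(lx)
  ssm_pca(ctr$centered, centering = ctr, center_tol = center_tol)
}
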