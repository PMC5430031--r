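#' Bootstrap voxelwise Z-map of pattern reliability
#'
#' Resamples subjects with replacement and reruns the entire SSM regression
#' on each replicate — log transform, double-centering, PCA, AIC subset
#' selection (unless a fixed subset is given), pattern composition.  Each
#' replicate pattern's sign is aligned to the point-estimate pattern (PCA
#' and regression signs flip freely across resamples; without alignment the
#' accumulated mean and SD are meaningless).  The voxelwise Z-score is the
#' bootstrap mean over the bootstrap SD, capped at `±z_cap`; voxels with
#' essentially zero SD get `sign(mean) * z_cap`.
#'
#' Randomness is governed by a single master seed that draws one sub-seed
#' per iteration up front, so replicates are reproducible independent of
#' execution order.  A resample with fewer than 3 unique subjects (or one
#' on which the regression degenerates) is redrawn, and the redraw is
#' counted in the run log.
#'
#' @param gmv a [gmv_matrix] or plain subjects x voxels matrix.
#' @param log_wmh,tiv response and head-size covariate, one value per
#'   subject.
#' @param n_iterations number of bootstrap replicates (default 500).
#' @param seed master seed (default 1).
#' @param z_crit threshold defining the reliable-voxel masks (default 2).
#' @param z_cap cap on |Z| to keep degenerate-SD voxels finite (default 50).
#' @param k_max,max_subset,use_aicc selection settings, as in
#'   [select_pattern()].
#' @param fixed_subset optional integer indices: skip per-replicate subset
#'   selection and always regress on these components of the replicate PCA.
#' @param numerator `"mean"` (default; bootstrap mean over SD) or
#'   `"point"` (point-estimate pattern over bootstrap SD).
#' @param offset_policy,epsilon see [log_transform()].
#' @return Object of class `"ssm_zmap"`: list with `mean`, `sd`, `z`,
#'   `pos_mask`, `neg_mask`, `pattern` (the point-estimate pattern),
#'   `n_iterations`, `seed`, `z_crit`, `z_cap`, `log` (per-iteration
#'   data.frame: iteration, subset, r2, redraws).
#' @export
bootstrap_zmap <- function(gmv, log_wmh, tiv, n_iterations = 500L, seed = 1L,
                           z_crit = 2, z_cap = 50,
                           k_max = 8L, max_subset = 4L, use_aicc = FALSE,
                           fixed_subset = NULL, numerator = c("mean", "point"),
                           offset_policy = "strict", epsilon = NULL) {
  numerator <- match.arg(numerator)
  x <- if (inherits(gmv, "gmv_matrix")) gmv$data else as.matrix(gmv)
  n <- nrow(x); p <- ncol(x)
  if (n < 10L) stop("need at least 10 subjects to bootstrap")
  n_iterations <- as.integer(n_iterations)
  if (n_iterations < 2L) stop("need at least 2 iterations")
  if (length(log_wmh) != n || length(tiv) != n)
    stop("log_wmh and tiv must have one value per subject")

  lx <- log_transform(x, offset_policy, epsilon)

  # point estimate on the full sample
  dec0 <- ssm_pca(double_center(lx)$centered)
  fit_one <- function(dec, y, tv) {
    if (is.null(fixed_subset)) {
      sel <- select_pattern(dec, y, tv, k_max = k_max,
                            max_subset = max_subset, use_aicc = use_aicc)
      S <- sel$selected
      betas <- sel$betas[paste0("comp", S)]
      r2 <- sel$r2
    } else {
      S <- as.integer(fixed_subset)
      f <- ols_fit(cbind(1, dec$ssf[, S, drop = FALSE], tv), y)
      betas <- f$beta[1L + seq_along(S)]
      r2 <- 1 - f$rss / sum((y - mean(y))^2)
    }
    list(pattern = compose_pattern(dec, S, betas), subset = S, r2 = r2)
  }
  pt <- fit_one(dec0, log_wmh, tiv)
  pattern0 <- pt$pattern

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  iter_seeds <- sample.int(.Machine$integer.max - 1L, n_iterations)

  s1 <- numeric(p); s2 <- numeric(p)
  log_subset <- character(n_iterations)
  log_r2 <- numeric(n_iterations)
  log_redraws <- integer(n_iterations)
  for (b in seq_len(n_iterations)) {
    set.seed(iter_seeds[b])
    redraws <- 0L
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(idx)) >= 3L) {
        rep_fit <- tryCatch(
          fit_one(ssm_pca(double_center(lx[idx, , drop = FALSE])$centered),
                  log_wmh[idx], tiv[idx]),
          error = function(e) NULL)
        if (!is.null(rep_fit)) break
      }
      redraws <- redraws + 1L
      if (redraws > 100L) stop("bootstrap iteration ", b,
                               " failed after 100 redraws")
    }
    w <- rep_fit$pattern
    if (sum(w * pattern0) < 0) w <- -w
    s1 <- s1 + w
    s2 <- s2 + w^2
    log_subset[b] <- paste(rep_fit$subset, collapse = ",")
    log_r2[b] <- rep_fit$r2
    log_redraws[b] <- redraws
  }

  m <- s1 / n_iterations
  v <- (s2 - n_iterations * m^2) / (n_iterations - 1)
  sdv <- sqrt(pmax(v, 0))
  num <- if (numerator == "mean") m else pattern0
  z <- ifelse(sdv < 1e-12, sign(num) * z_cap,
              pmin(pmax(num / sdv, -z_cap), z_cap))
  masks <- threshold_zmap_vec(z, z_crit)
  structure(
    list(mean = m, sd = sdv, z = z,
         pos_mask = masks$pos_mask, neg_mask = masks$neg_mask,
         pattern = pattern0, subset = pt$subset,
         n_iterations = n_iterations, seed = seed,
         z_crit = z_crit, z_cap = z_cap, numerator = numerator,
         log = data.frame(iteration = seq_len(n_iterations),
                          subset = log_subset, r2 = log_r2,
                          redraws = log_redraws)),
    class = "ssm_zmap")
}

threshold_zmap_vec <- function(z, z_crit) {
  list(pos_mask = z >= z_crit, neg_mask = z <= -z_crit)
}

#' Threshold a bootstrap Z-map into reliable-voxel masks
#'
#' Voxels with `Z >= z_crit` form the positive mask (relative GMV
#' preservation with greater WMH burden when the pattern is oriented to
#' predict log WMH); `Z <= -z_crit` forms the negative mask (reduced GMV).
#'
#' @param zmap an `"ssm_zmap"` (or numeric Z vector).
#' @param z_crit positive threshold (default 2).
#' @return List with logical `pos_mask` and `neg_mask`.
#' @export
threshold_zmap <- function(zmap, z_crit = 2) {
  if (z_crit <= 0) stop("z_crit must be > 0")
  z <- if (inherits(zmap, "ssm_zmap")) zmap$z else as.numeric(zmap)
  threshold_zmap_vec(z, z_crit)
}

#' @export
print.ssm_zmap <- function(x, ...) {
  cat("Bootstrap SSM Z-map:", length(x$z), "voxels,",
      x$n_iterations, "iterations (seed", paste0(x$seed, ")"), "\n")
  cat(sprintf("  |Z| >= %g: %d positive, %d negative voxels (cap %g)\n",
              x$z_crit, sum(x$pos_mask), sum(x$neg_mask), x$z_cap))
  mode_sub <- names(sort(table(x$log$subset), decreasing = TRUE))[1]
  cat("  modal replicate subset: {", mode_sub, "}; ",
      sum(x$log$redraws), " redraw(s)\n", sep = "")
  invisible(x)
}
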