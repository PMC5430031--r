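#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study conditions the analysis assumes: 64 subjects
#' in three ordered blood-pressure groups of 21/22/21, a compact brain-like
#' mask of about 2,000 voxels on a 20^3 grid, three orthogonalized smooth
#' spatial covariance patterns, the first pattern's subject loading tied to
#' blood-pressure group, age and education, and a log WMH response whose
#' population correlation with that loading is calibrated so the selected
#' pattern model explains roughly a third of the variance in log WMH
#' (population adjusted R^2 about 0.345).
#'
#' @param n_subjects cohort size (default 64).
#' @param grid_shape 3D grid (default `c(20, 20, 20)`).
#' @param voxel_size_mm isotropic voxel size (default 8 mm, whole-brain
#'   scale on a 20^3 grid).
#' @param mask_fraction fraction of grid voxels in the ellipsoidal mask
#'   (default 0.25, i.e. 2,000 voxels on the default grid).
#' @param n_patterns number of planted spatial patterns K (default 3).
#' @param pattern_kind `"blobs"` (Gaussian blobs, default) or `"block"`
#'   (rectangular patches).
#' @param pattern_sigma_vox Gaussian blob radius in voxels (default 2).
#'   Blob centres are drawn with a minimum pairwise separation of
#'   `3.5 * pattern_sigma_vox`, emulating anatomically distinct networks.
#' @param loading_sds residual SD of each pattern's subject loading
#'   (default `c(2, 1.5, 1.2)`).
#' @param noise_sd voxelwise Gaussian noise SD in log space (default 0.18,
#'   the between-subject residual scale of smoothed log VBM maps; together
#'   with `loading_sds` this puts the leading planted component modestly
#'   above the random-matrix eigenvalue floor, as in real data).
#' @param smoothing_fwhm_mm optional FWHM (mm) of a Gaussian kernel applied
#'   to the voxelwise noise field, emulating the spatial smoothness of
#'   preprocessed VBM residuals; the smoothed field is rescaled so the
#'   per-voxel noise SD stays `noise_sd`.  `NULL` (default) keeps the noise
#'   independent across voxels.
#' @param target_r population correlation between the informative loading
#'   combination and log WMH (default 0.61; with one informative component
#'   plus TIV at n = 64 this puts the population adjusted R^2 near 0.345).
#' @param y_loading_weights weights defining which loadings drive log WMH
#'   (default `c(1, 0, 0)`: only pattern 1 is informative).
#' @param group_sizes subjects per ordered BP group, normotensive /
#'   controlled / uncontrolled (default `c(21, 22, 21)`).
#' @param group_shift added to loading 1's mean per ordered group step
#'   (default `0.8 * loading_sds[1]`).
#' @param age_slope loading-1 change per year of age (default 0.04).
#' @param education_shift loading-1 shift for low education (default 0.5).
#' @param age_mean,age_sd,age_range cohort age distribution (72 +/- 7,
#'   clamped to 60–86).
#' @param tiv_mean_cc,tiv_sd_cc intracranial volume distribution
#'   (1400 +/- 120 cc).
#' @param log_wmh_mean,log_wmh_sd distribution of log WMH (% of TIV);
#'   defaults `log(0.55)` and 1.0 match a WMH brain fraction of roughly
#'   0.66 +/- 0.7 %.
#' @param cognition_effects named slopes of the four domain Z-scores on the
#'   standardized informative loading (defaults: memory -0.28, executive
#'   -0.32, speed 0, language 0).
#' @param cognition_noise_sd residual SD of the domain Z-scores (0.75).
#' @param seed master seed (default 1).
#' @return A list of class `"ssm_synthetic_config"`.
#' @export
synthetic_config <- function(n_subjects = 64L,
                             grid_shape = c(20L, 20L, 20L),
                             voxel_size_mm = 8,
                             mask_fraction = 0.25,
                             n_patterns = 3L,
                             pattern_kind = c("blobs", "block"),
                             pattern_sigma_vox = 2,
                             loading_sds = c(2, 1.5, 1.2),
                             noise_sd = 0.18,
                             smoothing_fwhm_mm = NULL,
                             target_r = 0.61,
                             y_loading_weights = c(1, 0, 0),
                             group_sizes = NULL,
                             group_shift = 0.8 * loading_sds[1],
                             age_slope = 0.04,
                             education_shift = 0.5,
                             age_mean = 72, age_sd = 7,
                             age_range = c(60, 86),
                             tiv_mean_cc = 1400, tiv_sd_cc = 120,
                             log_wmh_mean = log(0.55), log_wmh_sd = 1,
                             cognition_effects = c(memory = -0.28,
                                                   executive = -0.32,
                                                   speed = 0, language = 0),
                             cognition_noise_sd = 0.75,
                             seed = 1L) {
  pattern_kind <- match.arg(pattern_kind)
  if (is.null(group_sizes)) {
    if (n_subjects == 64L) group_sizes <- c(21L, 22L, 21L)
    else {
      base <- n_subjects %/% 3L
      group_sizes <- c(base, n_subjects - 2L * base, base)
    }
  }
  cfg <- list(n_subjects = as.integer(n_subjects),
              grid_shape = as.integer(grid_shape),
              voxel_size_mm = voxel_size_mm,
              mask_fraction = mask_fraction,
              n_patterns = as.integer(n_patterns),
              pattern_kind = pattern_kind,
              pattern_sigma_vox = pattern_sigma_vox,
              loading_sds = rep_len(loading_sds, n_patterns),
              noise_sd = noise_sd,
              smoothing_fwhm_mm = smoothing_fwhm_mm,
              target_r = target_r,
              y_loading_weights = rep_len(y_loading_weights, n_patterns),
              group_sizes = as.integer(group_sizes),
              group_shift = group_shift,
              age_slope = age_slope,
              education_shift = education_shift,
              age_mean = age_mean, age_sd = age_sd, age_range = age_range,
              tiv_mean_cc = tiv_mean_cc, tiv_sd_cc = tiv_sd_cc,
              log_wmh_mean = log_wmh_mean, log_wmh_sd = log_wmh_sd,
              cognition_effects = cognition_effects,
              cognition_noise_sd = cognition_noise_sd,
              seed = as.integer(seed))
  if (sum(cfg$group_sizes) != cfg$n_subjects)
    stop("group_sizes must sum to n_subjects")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (abs(cfg$target_r) >= 1) stop("|target_r| must be < 1")
  if (cfg$n_patterns < 1L) stop("need at least one pattern")
  class(cfg) <- "ssm_synthetic_config"
  cfg
}

# Ellipsoidal mask with exactly round(fraction * prod(grid)) voxels:
# normalized distance from grid centre, ties broken by raster order.
synthetic_mask <- function(grid_shape, mask_fraction) {
  k <- max(1L, round(mask_fraction * prod(grid_shape)))
  ctr <- (grid_shape + 1) / 2
  co <- as.matrix(expand.grid(x = seq_len(grid_shape[1]),
                              y = seq_len(grid_shape[2]),
                              z = seq_len(grid_shape[3])))
  d2 <- ((co[, 1] - ctr[1]) / grid_shape[1])^2 +
        ((co[, 2] - ctr[2]) / grid_shape[2])^2 +
        ((co[, 3] - ctr[3]) / grid_shape[3])^2
  sel <- order(d2, seq_along(d2))[seq_len(k)]
  mask <- array(FALSE, dim = grid_shape)
  mask[sel] <- TRUE
  mask
}

# Separable 3D Gaussian convolution (zero padded), rescaled so a unit-SD
# white field keeps unit voxelwise SD away from the volume edges.
gaussian_smooth_3d <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(arr)
  for (ax in 1:3) {
    arr <- apply(arr, setdiff(1:3, ax), function(v) {
      pad <- numeric(r)
      stats::filter(c(pad, v, pad), k, sides = 2)[(r + 1):(r + length(v))]
    })
    arr <- aperm(array(arr, dim = c(d[ax], d[setdiff(1:3, ax)])),
                 order(c(ax, setdiff(1:3, ax))))
  }
  arr / sqrt(sum(k^2))^3
}

# Smooth blob (or block) over the masked voxels around a centre coordinate.
pattern_field <- function(coords, centre, kind, sigma) {
  d2 <- rowSums(sweep(coords, 2L, centre)^2)
  if (kind == "blobs") exp(-d2 / (2 * sigma^2))
  else as.numeric(sqrt(d2) <= 1.5 * sigma)
}

#' Simulate a synthetic cohort with planted covariance patterns
#'
#' Generates a subjects x voxels GMV dataset following the generative model
#' the pipeline assumes: in log space, a smooth mean map plus K
#' orthonormalized spatial patterns weighted by per-subject loadings plus
#' Gaussian noise (so the pipeline's log transform recovers an exactly
#' linear model).  Loading 1 carries the clinical structure — an ordered
#' blood-pressure group shift, an age slope, and an education shift — and
#' log WMH is drawn with a configurable population correlation to the
#' informative loading combination.  Blood pressures, medication counts and
#' hypertension history are drawn consistently with each subject's group,
#' so [classify_bp_group()] reproduces the assignment exactly.
#'
#' @param config an [synthetic_config()] object.
#' @return Object of class `"ssm_synthetic"`: list with `gmv` (a
#'   [gmv_matrix]), `covariates` (full covariate table, derived columns
#'   filled), `true_patterns` (K x n_voxels orthonormal rows),
#'   `true_loadings` (n x K), `true_support` (list of logical voxel
#'   vectors), `mean_log` (voxel vector), `config`.
#' @export
simulate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "ssm_synthetic_config"))
  cfg <- config
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)

  mask <- synthetic_mask(cfg$grid_shape, cfg$mask_fraction)
  coords <- mask_voxel_index(mask)
  p <- nrow(coords)
  if (cfg$n_patterns > p) stop("more patterns than mask voxels")
  n <- cfg$n_subjects
  K <- cfg$n_patterns

  # blob centres: interior mask voxels with minimum pairwise separation
  # (distinct networks); best-separated of 200 candidate placements
  ctr <- (cfg$grid_shape + 1) / 2
  d2 <- rowSums(sweep(coords, 2L, ctr)^2)
  interior <- which(d2 <= stats::quantile(d2, 0.5))
  min_sep <- 3.5 * cfg$pattern_sigma_vox
  best_centres <- NULL; best_sep <- -Inf
  for (try in seq_len(200L)) {
    cand <- coords[sample(interior, K), , drop = FALSE]
    sep <- if (K == 1L) Inf else min(stats::dist(cand))
    if (sep > best_sep) { best_sep <- sep; best_centres <- cand }
    if (sep >= min_sep) break
  }
  centres <- best_centres

  raw <- vapply(seq_len(K), function(k)
    pattern_field(coords, centres[k, ], cfg$pattern_kind,
                  cfg$pattern_sigma_vox),
    numeric(p))
  # support at half maximum (FWHM), the usual definition of a blob's extent
  support <- lapply(seq_len(K), function(k)
    raw[, k] >= 0.5 * max(raw[, k]))
  # Gram–Schmidt orthonormalization, keeping each vector aligned with its blob
  Q <- matrix(0, p, K)
  for (k in seq_len(K)) {
    v <- raw[, k]
    if (k > 1L) v <- v - Q[, 1:(k - 1), drop = FALSE] %*%
        crossprod(Q[, 1:(k - 1), drop = FALSE], v)
    nv <- sqrt(sum(v^2))
    if (nv < 1e-10) stop("degenerate pattern ", k,
                         " (blobs coincide); change the seed or sigma")
    v <- v / nv
    if (sum(v * raw[, k]) < 0) v <- -v
    Q[, k] <- v
  }
  true_patterns <- t(Q)

  # smooth mean map: baseline GM density ~0.5, higher centrally
  mean_log <- log(0.5) + 0.2 * exp(-d2 / (2 * (0.45 * max(sqrt(d2)))^2))

  # clinical covariates -----------------------------------------------------
  group_code <- rep(0:2, times = cfg$group_sizes)
  age <- round(pmin(pmax(stats::rnorm(n, cfg$age_mean, cfg$age_sd),
                         cfg$age_range[1]), cfg$age_range[2]))
  low_edu <- stats::runif(n) < 35 / 64
  sex <- factor(ifelse(stats::runif(n) < 21 / 64, "male", "female"),
                levels = c("male", "female"))
  gc_z <- stats::rnorm(n, 0.08, 0.81)

  load_mat <- matrix(0, n, K)
  load_mat[, 1] <- cfg$group_shift * group_code +
    cfg$age_slope * (age - cfg$age_mean) +
    cfg$education_shift * low_edu +
    stats::rnorm(n, 0, cfg$loading_sds[1])
  if (K > 1L)
    for (k in 2:K) load_mat[, k] <- stats::rnorm(n, 0, cfg$loading_sds[k])

  combo <- as.numeric(load_mat %*% cfg$y_loading_weights)
  z1 <- (combo - mean(combo)) / stats::sd(combo)
  y <- cfg$log_wmh_mean + cfg$log_wmh_sd *
    (cfg$target_r * z1 + sqrt(1 - cfg$target_r^2) * stats::rnorm(n))

  tiv <- stats::rnorm(n, cfg$tiv_mean_cc, cfg$tiv_sd_cc)
  tbv <- tiv * stats::rnorm(n, 0.80, 0.02)
  gmv_cc <- tbv * stats::rnorm(n, 0.56, 0.015)
  wmh <- tiv * exp(y) / 100

  # blood pressure consistent with the assigned group
  sbp <- dbp <- numeric(n); meds <- integer(n); hist <- logical(n)
  g0 <- group_code == 0; g1 <- group_code == 1; g2 <- group_code == 2
  sbp[g0] <- pmin(stats::rnorm(sum(g0), 122, 8), 138)
  dbp[g0] <- pmin(stats::rnorm(sum(g0), 76, 6), 88)
  sbp[g1] <- pmin(stats::rnorm(sum(g1), 128, 6), 138)
  dbp[g1] <- pmin(stats::rnorm(sum(g1), 80, 5), 88)
  sbp[g2] <- stats::rnorm(sum(g2), 152, 9)
  dbp[g2] <- stats::rnorm(sum(g2), 88, 7)
  fixup <- g2 & sbp < 140 & dbp < 90
  sbp[fixup] <- 140 + abs(stats::rnorm(sum(fixup), 4, 3))
  hist[g1 | g2] <- TRUE
  meds[g1] <- 1L + stats::rbinom(sum(g1), 1L, 5 / 22)
  meds[g2] <- sample(0:3, sum(g2), replace = TRUE, prob = c(9, 6, 6, 1) / 22)
  sbp <- round(sbp, 1); dbp <- round(dbp, 1)

  ef <- unname(cfg$cognition_effects[c("memory", "executive",
                                       "speed", "language")])
  zl <- (load_mat[, 1] - mean(load_mat[, 1])) / stats::sd(load_mat[, 1])
  cog <- outer(zl, ef) +
    matrix(stats::rnorm(n * 4, 0, cfg$cognition_noise_sd), n, 4)

  ids <- sprintf("S%03d", seq_len(n))
  covariates <- data.frame(
    id = ids, age = age, sex = sex, low_education = low_edu, gc_z = gc_z,
    sbp = sbp, dbp = dbp, htn_history = hist, n_antihypertensives = meds,
    tiv_cc = tiv, tbv_cc = tbv, wmh_cc = wmh,
    memory_z = cog[, 1], exec_z = cog[, 2],
    speed_z = cog[, 3], language_z = cog[, 4],
    stringsAsFactors = FALSE)
  covariates <- add_derived_covariates(covariates, gmv_cc = gmv_cc)

  # image data: linear model in log space, exponentiated
  if (is.null(cfg$smoothing_fwhm_mm)) {
    noise <- matrix(stats::rnorm(n * p, 0, cfg$noise_sd), n, p)
  } else {
    sigma_vox <- cfg$smoothing_fwhm_mm / (2 * sqrt(2 * log(2))) /
      cfg$voxel_size_mm
    lin <- mask_linear_index(mask)
    noise <- t(vapply(seq_len(n), function(i) {
      field <- array(stats::rnorm(prod(cfg$grid_shape)), cfg$grid_shape)
      gaussian_smooth_3d(field, sigma_vox)[lin]
    }, numeric(p))) * cfg$noise_sd
  }
  log_gmv <- matrix(mean_log, n, p, byrow = TRUE) +
    load_mat %*% true_patterns + noise
  vx <- cfg$voxel_size_mm
  affine <- diag(c(vx, vx, vx, 1))
  affine[1:3, 4] <- -vx * cfg$grid_shape / 2
  gmv <- gmv_matrix(exp(log_gmv), ids, mask, affine)

  structure(
    list(gmv = gmv, covariates = covariates,
         true_patterns = true_patterns, true_loadings = load_mat,
         true_support = support, mean_log = mean_log, config = cfg),
    class = "ssm_synthetic")
}

#' @export
print.ssm_synthetic <- function(x, ...) {
  cfg <- x$config
  cat("Synthetic SSM cohort:", cfg$n_subjects, "subjects,",
      ncol(x$gmv$data), "masked voxels,", cfg$n_patterns,
      "planted patterns (seed", paste0(cfg$seed, ")"), "\n")
  cat("  BP groups (normo/controlled/uncontrolled):",
      paste(cfg$group_sizes, collapse = "/"), "\n")
  cat(sprintf("  target corr(loading 1, logWMH) = %.3f; noise SD = %g\n",
              cfg$target_r, cfg$noise_sd))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Writes per-subject GMV NIfTI volumes, the mask, the covariate CSV, the
#' planted pattern maps, and a ground-truth YAML (config echo, seed, true
#' loadings, support sizes).  The files round-trip through
#' [load_gmv_dataset()] / [load_covariates()].
#'
#' @param ds an `"ssm_synthetic"` dataset.
#' @param out_dir output directory (created if needed).
#' @return Named list of the written paths, invisibly.
#' @export
write_dataset <- function(ds, out_dir) {
  stopifnot(inherits(ds, "ssm_synthetic"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gmv <- ds$gmv
  mask_path <- file.path(out_dir, "mask.nii.gz")
  mask_img <- RNifti::asNifti(array(as.numeric(gmv$mask),
                                    dim = gmv$geometry$dim))
  RNifti::sform(mask_img) <- structure(gmv$geometry$affine, code = 2L)
  RNifti::writeNifti(mask_img, mask_path, datatype = "uint8")

  img_paths <- file.path(out_dir,
                         sprintf("%s_gmv.nii.gz", gmv$subject_ids))
  for (i in seq_along(img_paths))
    save_voxel_map(gmv$data[i, ], gmv, img_paths[i])

  truth_paths <- file.path(out_dir,
                           sprintf("true_pattern_%d.nii.gz",
                                   seq_len(nrow(ds$true_patterns))))
  for (k in seq_along(truth_paths))
    save_voxel_map(ds$true_patterns[k, ], gmv, truth_paths[k])

  cov_path <- file.path(out_dir, "covariates.csv")
  cov <- ds$covariates
  cov$bp_group <- as.character(cov$bp_group)
  utils::write.csv(cov, cov_path, row.names = FALSE)

  truth_path <- file.path(out_dir, "ground_truth.yaml")
  yaml::write_yaml(list(
    config = unclass(ds$config),
    true_loadings = apply(ds$true_loadings, 1, as.numeric, simplify = FALSE),
    support_sizes = vapply(ds$true_support, sum, integer(1))),
    truth_path)

  invisible(list(images = img_paths, mask = mask_path,
                 covariates = cov_path, truth = truth_path,
                 patterns = truth_paths))
}
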