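test_that("cohort simulation is fully determined by its seed", {
  a <- simulate_cohort(small_cohort_config(seed = 61))
  b <- simulate_cohort(small_cohort_config(seed = 61))
  c <- simulate_cohort(small_cohort_config(seed = 62))
  expect_identical(a$gmv$data, b$gmv$data)
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$true_patterns, b$true_patterns)
  expect_false(identical(a$gmv$data, c$gmv$data))
})

test_that("the generative model is exactly linear in log space", {
  # zero noise, one pattern: log-transformed double-centered data is rank 1
  cfg <- small_cohort_config(seed = 63, n_subjects = 16, n_patterns = 1,
                             noise_sd = 0, loading_sds = 2,
                             y_loading_weights = 1)
  ds <- simulate_cohort(cfg)
  dec <- ssm_decompose(ds$gmv)
  expect_gt(dec$eigenvalues[1], 1e-6)
  expect_lt(dec$eigenvalues[2] / dec$eigenvalues[1], 1e-16)

  # with noise 0 the reconstruction identity holds voxel by voxel
  recon <- matrix(ds$mean_log, 16, ncol(ds$gmv$data), byrow = TRUE) +
    ds$true_loadings %*% ds$true_patterns
  expect_equal(log(ds$gmv$data), recon, tolerance = 1e-12,
               ignore_attr = TRUE)

  # planted patterns are orthonormal and supports are within the mask
  G <- ds$true_patterns %*% t(ds$true_patterns)
  expect_equal(G, diag(nrow(G)), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("the loading-response correlation approaches its target", {
  cfg <- small_cohort_config(seed = 64, n_subjects = 10000)
  ds <- simulate_cohort(cfg)
  r <- cor(ds$true_loadings[, 1], ds$covariates$log_wmh)
  expect_lt(abs(r - cfg$target_r), 0.05)
})

test_that("clinical covariates are internally consistent", {
  ds <- simulate_cohort(small_cohort_config(seed = 65, n_subjects = 64))
  cov <- ds$covariates
  cfg <- ds$config
  # classification recovers the assigned ordered groups exactly
  expect_equal(as.character(cov$bp_group),
               rep(c("normotensive", "controlled", "uncontrolled"),
                   times = cfg$group_sizes))
  expect_equal(as.character(classify_bp_group(cov$htn_history,
                                              cov$n_antihypertensives > 0,
                                              cov$sbp, cov$dbp)),
               as.character(cov$bp_group))
  # WMH volume, percent of TIV and its log are mutually consistent
  expect_equal(cov$wmh_pct_tiv, 100 * cov$wmh_cc / cov$tiv_cc)
  expect_equal(cov$log_wmh, log(cov$wmh_pct_tiv))
  expect_true(all(cov$wmh_cc < cov$tbv_cc & cov$tbv_cc < cov$tiv_cc))
  expect_true(all(cov$gmf > 0.4 & cov$gmf < 0.7))
  expect_equal(sum(is.na(cov)), 0L)
})

test_that("datasets round-trip through disk", {
  dir <- withr::local_tempdir()
  ds <- simulate_cohort(small_cohort_config(seed = 66, n_subjects = 8))
  paths <- write_dataset(ds, dir)
  # bookkeeping: n subject maps + mask + K truth maps + 2 tables
  expect_length(paths$images, 8L)
  expect_length(paths$patterns, ds$config$n_patterns)
  expect_equal(length(list.files(dir)),
               8L + 1L + ds$config$n_patterns + 2L)

  gmv2 <- load_gmv_dataset(paths$images, paths$mask,
                           subject_ids = ds$gmv$subject_ids)
  expect_equal(gmv2$data, ds$gmv$data, tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(gmv2$voxel_index, ds$gmv$voxel_index)
  expect_equal(gmv2$geometry$affine, ds$gmv$geometry$affine,
               ignore_attr = TRUE)

  cov2 <- load_covariates(paths$covariates)   # passes schema validation
  cov2 <- add_derived_covariates(cov2)
  expect_equal(cov2$log_wmh, ds$covariates$log_wmh, tolerance = 1e-8)
  expect_equal(as.character(cov2$bp_group),
               as.character(ds$covariates$bp_group))

  truth <- yaml::read_yaml(paths$truth)
  expect_equal(truth$config$seed, 66)
  expect_equal(truth$support_sizes,
               vapply(ds$true_support, sum, integer(1)))
})

test_that("optional noise smoothing induces spatial autocorrelation", {
  base <- simulate_cohort(small_cohort_config(seed = 67, n_subjects = 12,
                                              loading_sds = c(0, 0, 0)))
  sm <- simulate_cohort(small_cohort_config(seed = 67, n_subjects = 12,
                                            loading_sds = c(0, 0, 0),
                                            smoothing_fwhm_mm = 20))
  # correlation between log values at adjacent masked voxels
  adjacency_cor <- function(ds) {
    lx <- log(ds$gmv$data)
    idx <- ds$gmv$voxel_index
    nbr <- match(
      paste(idx[, 1] + 1L, idx[, 2], idx[, 3]),
      paste(idx[, 1], idx[, 2], idx[, 3]))
    ok <- !is.na(nbr)
    cor(as.vector(lx[, ok]), as.vector(lx[, nbr[ok]]))
  }
  expect_lt(abs(adjacency_cor(base)), 0.2)
  expect_gt(adjacency_cor(sm), 0.5)
  # per-voxel noise scale is preserved by the rescaled kernel
  expect_equal(sd(log(sm$gmv$data)), sd(log(base$gmv$data)),
               tolerance = 0.15)
})

test_that("infeasible configurations are rejected", {
  expect_error(synthetic_config(n_subjects = 10, group_sizes = c(5, 5, 5)),
               "sum")
  expect_error(synthetic_config(target_r = 1), "target_r")
  expect_error(synthetic_config(noise_sd = -1), "noise_sd")
  expect_error(simulate_cohort(
    synthetic_config(n_subjects = 6, grid_shape = c(3L, 3L, 3L),
                     mask_fraction = 0.1, n_patterns = 20)),
    "patterns")
})
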