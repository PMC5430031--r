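test_that("AIC formula counts the intercept and penalizes extra predictors", {
  expect_equal(aic_score(rss = 64, n = 64, k = 3), 8)
  expect_equal(aic_score(rss = 64, n = 64, k = 4) -
               aic_score(rss = 64, n = 64, k = 3), 2)
  # correction term 2(k+1)(k+2)/(n-k-2) with k = 3, n = 64: 40/59
  expect_equal(aic_score(rss = 64, n = 64, k = 3, use_aicc = TRUE),
               8 + 2 * 4 * 5 / 59)
  expect_error(aic_score(0, 64, 3), "rss")
  expect_error(aic_score(10, 6, 4), "n > k")
})

test_that("a noiseless response selects its generating component exactly", {
  ds <- simulate_cohort(small_cohort_config(seed = 11))
  dec <- ssm_decompose(ds$gmv)
  set.seed(1)
  tiv <- ds$covariates$tiv_cc
  y <- dec$ssf[, 1]
  sel <- select_pattern(dec, y, tiv, k_max = 6, max_subset = 3)
  expect_equal(sel$selected, 1L)
  expect_equal(sel$r, 1, tolerance = 1e-10)
  expect_identical(sel$aic, -Inf)
})

test_that("the exhaustive search enumerates every admissible subset", {
  ds <- simulate_cohort(small_cohort_config(seed = 12))
  dec <- ssm_decompose(ds$gmv)
  sel <- select_pattern(dec, ds$covariates$log_wmh, ds$covariates$tiv_cc,
                        k_max = 6, max_subset = 3)
  expect_equal(nrow(sel$candidates),
               choose(6, 1) + choose(6, 2) + choose(6, 3))  # 41
  # monotonicity: adding a component never increases the RSS
  cand <- sel$candidates
  for (i in seq_len(nrow(cand))) {
    S <- as.integer(strsplit(cand$subset[i], ",")[[1]])
    if (length(S) == 1L) next
    for (drop in seq_along(S)) {
      sub <- paste(S[-drop], collapse = ",")
      expect_lte(cand$rss[i], cand$rss[cand$subset == sub] + 1e-10)
    }
  }
})

test_that("selection agrees with an independent exhaustive-search oracle", {
  for (seed in 1:10) {
    ds <- simulate_cohort(small_cohort_config(seed = seed))
    dec <- ssm_decompose(ds$gmv)
    y <- ds$covariates$log_wmh; tiv <- ds$covariates$tiv_cc
    sel <- select_pattern(dec, y, tiv, k_max = 6, max_subset = 3)
    ora <- oracle_select(dec$ssf, y, tiv, k_max = 6, max_subset = 3)
    expect_identical(sel$selected, as.integer(ora$S))
    expect_equal(sel$aic, ora$aic, tolerance = 1e-8)
  }
})

test_that("patterns compose linearly from selected loadings", {
  ds <- simulate_cohort(small_cohort_config(seed = 13, n_subjects = 12))
  dec <- ssm_decompose(ds$gmv)
  expect_equal(compose_pattern(dec, 2, 1), dec$loadings[2, ])
  expect_equal(compose_pattern(dec, c(1, 3), c(0, 0)),
               numeric(dec$n_voxels))
  w <- compose_pattern(dec, c(1, 2), c(2, -1))
  expect_equal(w, 2 * dec$loadings[1, ] - dec$loadings[2, ], tolerance = 1e-12)
  expect_error(compose_pattern(dec, 99, 1), "out of range")
  expect_error(compose_pattern(dec, c(1, 2), 1), "one beta")
})

test_that("subject scores are centered projections with exact OLS algebra", {
  # hand example: projection of the centered rows on the first axis
  c2 <- matrix(c(-1, 0, 1, 1, 0, -1), 2, 3, byrow = TRUE)
  dec2 <- ssm_pca(c2)
  expect_equal(compute_subject_scores(dec2, c(1, 0, 0), standardize = FALSE),
               c(-1, 1))
  expect_equal(compute_subject_scores(dec2, c(0, 0, 0), standardize = FALSE),
               c(0, 0))
  expect_error(compute_subject_scores(dec2, c(0, 0, 0)), "degenerate")
  expect_error(compute_subject_scores(dec2, c(1, 0)), "length")

  # identity: raw scores of the composed pattern equal the fitted response
  # minus intercept and TIV contribution (SSF = U * S convention)
  ds <- simulate_cohort(small_cohort_config(seed = 14))
  dec <- ssm_decompose(ds$gmv)
  y <- ds$covariates$log_wmh; tiv <- ds$covariates$tiv_cc
  sel <- select_pattern(dec, y, tiv, k_max = 6, max_subset = 3)
  w <- compose_pattern(dec, sel$selected,
                       sel$betas[paste0("comp", sel$selected)])
  raw <- compute_subject_scores(dec, w, standardize = FALSE)
  expect_equal(raw,
               sel$fitted - sel$betas["intercept"] - sel$betas["tiv"] * tiv,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(cor(raw, sel$fitted - sel$betas["tiv"] * tiv), 1,
               tolerance = 1e-8)
})

test_that("the fitted pattern model is a coherent S3 object", {
  ds <- simulate_cohort(small_cohort_config(seed = 15))
  fit <- ssm_pattern(ds$gmv, ds$covariates, k_max = 6, max_subset = 3)
  expect_s3_class(fit, "ssm_pattern")
  expect_equal(mean(fit$subject_scores), 0, tolerance = 1e-8)
  expect_equal(sd(fit$subject_scores), 1, tolerance = 1e-8)
  expect_equal(fit$pattern_weights,
               compose_pattern(fit$decomposition, fit$selected,
                               fit$betas[paste0("comp", fit$selected)]),
               tolerance = 1e-10)
  expect_gte(fit$r^2, fit$adj_r2)
  expect_named(coef(fit),
               c("intercept", paste0("comp", fit$selected), "tiv"))
  expect_equal(residuals(fit), fit$y - fitted(fit))
  expect_equal(predict(fit), fit$subject_scores)
  # prospective scoring reproduces training scores on the training data
  expect_equal(predict(fit, ds$gmv), fit$subject_scores, tolerance = 1e-8)
  expect_output(print(fit), "components selected")
  expect_output(print(summary(fit)), "Components only")

  # null association: adj R^2 hovers near zero across permuted responses
  set.seed(99)
  null_adj <- replicate(30, {
    yp <- sample(ds$covariates$log_wmh)
    select_pattern(fit$decomposition, yp, ds$covariates$tiv_cc,
                   k_max = 6, max_subset = 2)$adj_r2
  })
  expect_lt(abs(mean(null_adj)), 0.1)
})
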