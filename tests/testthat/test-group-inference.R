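test_that("blood pressure classification follows the clinical decision table", {
  cl <- function(h, m, s, d) as.character(classify_bp_group(h, m, s, d))
  # the three rules
  expect_equal(cl(TRUE, TRUE, 132, 84), "controlled")
  expect_equal(cl(TRUE, TRUE, 150, 85), "uncontrolled")
  expect_equal(cl(TRUE, FALSE, 150, 85), "uncontrolled")  # meds not required
  expect_equal(cl(FALSE, FALSE, 118, 76), "normotensive")
  # fall-throughs
  expect_equal(cl(FALSE, FALSE, 152, 96), "unclassified")
  expect_equal(cl(TRUE, FALSE, 132, 84), "unclassified")  # history, off meds
  expect_equal(cl(FALSE, TRUE, 118, 76), "unclassified")  # medicated, no history
  # boundary: exactly 140 or 90 counts as not controlled
  expect_equal(cl(TRUE, TRUE, 140, 80), "uncontrolled")
  expect_equal(cl(TRUE, TRUE, 130, 90), "uncontrolled")
  expect_equal(cl(TRUE, TRUE, 139.9, 89.9), "controlled")
  expect_equal(cl(FALSE, FALSE, 140, 89), "unclassified")
  # exhaustive sweep: the function is total and the four labels partition it
  grid <- expand.grid(h = c(TRUE, FALSE), m = c(TRUE, FALSE),
                      s = c(100, 139, 140, 141, 180),
                      d = c(70, 89, 90, 91, 110))
  out <- classify_bp_group(grid$h, grid$m, grid$s, grid$d)
  expect_false(anyNA(out))
  below <- grid$s < 140 & grid$d < 90
  expect_equal(out == "normotensive", !grid$h & !grid$m & below,
               ignore_attr = TRUE)
  expect_equal(out == "controlled", grid$h & grid$m & below,
               ignore_attr = TRUE)
  expect_equal(out == "uncontrolled", grid$h & !below, ignore_attr = TRUE)
  expect_true(is.ordered(out))
  expect_error(classify_bp_group(TRUE, TRUE, 40, 80), "onphysiologic")
  expect_error(classify_bp_group(TRUE, TRUE, 320, 80), "onphysiologic")
})

test_that("volumetric normalization matches hand arithmetic", {
  v <- derive_volumetrics(tbv_cc = 1125, tiv_cc = 1400, wmh_cc = 14)
  expect_equal(v$wmh_pct_tiv, 1)
  expect_equal(v$log_wmh, 0)
  expect_equal(derive_volumetrics(tbv_cc = 1200, tiv_cc = 1400,
                                  wmh_cc = 7)$log_wmh, log(0.5))
  expect_equal(derive_volumetrics(gmv_cc = 630, tbv_cc = 1125,
                                  tiv_cc = 1400, wmh_cc = 7)$gmf, 0.56)
  expect_error(derive_volumetrics(tbv_cc = 1200, tiv_cc = 1400, wmh_cc = 0),
               "zero WMH")
  fl <- derive_volumetrics(tbv_cc = 1200, tiv_cc = 1400, wmh_cc = 0,
                           wmh_floor_cc = 0.14)
  expect_equal(fl$log_wmh, log(0.01))
  expect_error(derive_volumetrics(tbv_cc = -1, tiv_cc = 1400, wmh_cc = 1),
               "positive")
})

test_that("ANCOVA group effect matches a nested normal-equations oracle", {
  # scores orthogonal to the group indicators given the covariates, with
  # nonzero residual variance => F exactly 0
  g <- factor(rep(c("normotensive", "controlled", "uncontrolled"), each = 4))
  set.seed(30)
  covs0 <- data.frame(age = rnorm(12, 72, 7), gc_z = rnorm(12))
  scores0 <- residuals(lm(rnorm(12) ~ g + age + gc_z, data = covs0))
  r0 <- ancova_group_effect(scores0, g, covs0)
  expect_equal(r0$f_stat, 0)
  expect_gt(var(scores0), 0)
  expect_equal(r0$dof[1], 2)

  # randomized 12-subject toy vs independent oracle
  set.seed(31)
  scores <- rnorm(12)
  covs <- data.frame(age = rnorm(12, 72, 7),
                     sex = factor(sample(c("male", "female"), 12, TRUE)),
                     low_education = runif(12) < 0.5,
                     gc_z = rnorm(12))
  r <- ancova_group_effect(scores, g, covs)
  Xc <- cbind(1, covs$age, covs$sex == "male", covs$low_education, covs$gc_z)
  X1 <- cbind(Xc, g == "normotensive", g == "uncontrolled")
  ora <- oracle_f_test(Xc, X1, scores)
  expect_equal(r$f_stat, ora$f, tolerance = 1e-8)
  expect_equal(r$p, ora$p, tolerance = 1e-8)
  expect_equal(r$dof, c(ora$df1, ora$df2))
  expect_equal(nrow(r$contrasts), 3L)
  expect_error(ancova_group_effect(scores, factor(rep("a", 12)), covs),
               "2 groups")
})

test_that("the ordinal trend test is a standardized slope on the group code", {
  g <- rep(0:2, times = c(4, 4, 4))
  covs <- data.frame(age = rep(c(60, 70, 80, 90), 3),
                     low_education = rep(c(TRUE, FALSE), 6))
  # constant scores: no trend, slope exactly 0
  r0 <- ordinal_trend_test(rep(1, 12), g, covs)
  expect_equal(r0$beta, 0)

  # scores equal to the group code: slope is the hand-computed value on the
  # standardized response, p at the machine floor
  z <- (g - mean(g)) / sd(g)
  r1 <- suppressWarnings(ordinal_trend_test(g, g, covs))
  expect_equal(r1$beta, sum((g - mean(g)) * z) / sum((g - mean(g))^2),
               tolerance = 1e-10)
  expect_lt(r1$p, 1e-12)

  # reversing the ordering flips the sign exactly
  set.seed(41)
  s <- rnorm(12) + 0.5 * g
  ra <- ordinal_trend_test(s, g, covs)
  rb <- ordinal_trend_test(s, 2 - g, covs)
  expect_equal(ra$beta, -rb$beta, tolerance = 1e-10)

  # against the normal-equations oracle
  zz <- (s - mean(s)) / sd(s)
  X <- cbind(1, g, covs$age, covs$low_education)
  expect_equal(ra$beta, oracle_ols(X, zz)$beta[2], tolerance = 1e-8)
  expect_error(ordinal_trend_test(s, rep(1, 12), covs), "one group")
})

test_that("cognitive associations match the oracle and Bonferroni family", {
  set.seed(51)
  n <- 10
  scores <- rnorm(n)
  covs <- data.frame(age = rnorm(n, 72, 6), low_education = runif(n) < 0.5)
  dz <- 0.5 * scores - 0.02 * covs$age + rnorm(n, 0, 0.5)
  r <- cognition_association(scores, dz, covs, m = 4)
  X <- cbind(1, scores, covs$age, covs$low_education)
  expect_equal(r$beta, oracle_ols(X, dz)$beta[2], tolerance = 1e-8)
  expect_equal(r$p_corrected, min(1, 4 * r$p))

  # orthogonal construction: residualized response has exactly zero slope
  resid_z <- residuals(lm(dz ~ scores + age + low_education, data = covs))
  r0 <- cognition_association(scores, resid_z, covs)
  expect_lt(abs(r0$beta), 1e-10)

  # the four-domain wrapper corrects every row by the family size
  ds <- simulate_cohort(small_cohort_config(seed = 52, n_subjects = 30))
  fit_scores <- rnorm(30)
  tab <- cognition_associations(fit_scores, ds$covariates)
  expect_equal(tab$domain, c("memory", "executive", "speed", "language"))
  expect_equal(tab$p_corrected, pmin(1, 4 * tab$p))
})

test_that("Bonferroni correction clamps at one", {
  expect_equal(bonferroni_correct(0.012, 4), 0.048)
  expect_equal(bonferroni_correct(0.004, 4), 0.016)
  expect_equal(bonferroni_correct(0.5, 4), 1)
  expect_equal(bonferroni_correct(c(0.01, 0.4), 4), c(0.04, 1))
  expect_error(bonferroni_correct(1.2, 4), "0, 1")
  expect_error(bonferroni_correct(0.1, 0), "m")
})
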