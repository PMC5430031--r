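#' Classify blood pressure control group
#'
#' Applies the cohort's classification rules to the mean of two seated
#' blood pressure measurements:
#' \itemize{
#'   \item \strong{normotensive} — no history of hypertension, not on
#'     antihypertensive medication, and mean pressure below 140/90;
#'   \item \strong{controlled} — history of hypertension, on medication,
#'     and mean pressure below 140 systolic \emph{and} 90 diastolic;
#'   \item \strong{uncontrolled} — history of hypertension and mean
#'     pressure at or above 140 systolic \emph{or} 90 diastolic;
#'   \item \strong{unclassified} — anything falling through the three rules
#'     (e.g. hypertensive-range pressure with no history, or a treated
#'     history currently off medication with normal pressure).
#' }
#' A pressure exactly at 140/90 counts as not controlled (clinical
#' convention; the boundary is otherwise unassigned).
#'
#' @param htn_history logical, reported history of hypertension.
#' @param on_medication logical, currently taking antihypertensives.
#' @param mean_sbp,mean_dbp mean systolic / diastolic pressure, mmHg.
#' @return Ordered factor with levels
#'   `normotensive < controlled < uncontrolled < unclassified` (the last
#'   level records subjects outside the three rules and is not part of the
#'   ordinal trend).  Vectorized over all arguments.
#' @export
classify_bp_group <- function(htn_history, on_medication, mean_sbp, mean_dbp) {
  k <- max(length(htn_history), length(on_medication),
           length(mean_sbp), length(mean_dbp))
  htn_history <- rep_len(as.logical(htn_history), k)
  on_medication <- rep_len(as.logical(on_medication), k)
  mean_sbp <- rep_len(as.numeric(mean_sbp), k)
  mean_dbp <- rep_len(as.numeric(mean_dbp), k)
  bad <- which(mean_sbp < 50 | mean_sbp > 300 | mean_dbp < 30 | mean_dbp > 200)
  if (length(bad))
    stop("nonphysiologic blood pressure at position(s) ",
         paste(bad, collapse = ", "))
  below <- mean_sbp < 140 & mean_dbp < 90
  out <- rep("unclassified", k)
  out[!htn_history & !on_medication & below] <- "normotensive"
  out[htn_history & on_medication & below] <- "controlled"
  out[htn_history & !below] <- "uncontrolled"
  factor(out, levels = bp_group_levels(), ordered = TRUE)
}

#' Normalized volumetric measures
#'
#' Gray matter fraction `gmf = gmv / tbv`; WMH volume as a percent of
#' intracranial volume `wmh_pct_tiv = 100 * wmh / tiv`; and its natural log
#' `log_wmh = ln(wmh_pct_tiv)`, the response used throughout the pattern
#' regression (raw WMH volumes are heavily right-skewed).
#'
#' @param gmv_cc total gray matter volume in cc (optional; `gmf` is `NA`
#'   when absent).
#' @param tbv_cc,tiv_cc total brain / intracranial volume in cc (> 0).
#' @param wmh_cc WMH volume in cc (>= 0).
#' @param wmh_floor_cc floor substituted for zero WMH volumes before the
#'   log; `NULL` (strict, default) makes a zero an error.
#' @return List with `gmf`, `wmh_pct_tiv`, `log_wmh`, vectorized.
#' @export
derive_volumetrics <- function(gmv_cc = NULL, tbv_cc, tiv_cc, wmh_cc,
                               wmh_floor_cc = NULL) {
  if (any(tbv_cc <= 0, na.rm = TRUE) || any(tiv_cc <= 0, na.rm = TRUE))
    stop("tbv_cc and tiv_cc must be strictly positive")
  if (any(wmh_cc < 0, na.rm = TRUE)) stop("wmh_cc must be non-negative")
  w <- wmh_cc
  zero <- !is.na(w) & w == 0
  if (any(zero)) {
    if (is.null(wmh_floor_cc))
      stop("zero WMH volume under strict policy; set wmh_floor_cc")
    w[zero] <- wmh_floor_cc
  }
  gmf <- if (is.null(gmv_cc)) rep(NA_real_, length(tbv_cc)) else gmv_cc / tbv_cc
  pct <- 100 * w / tiv_cc
  list(gmf = gmf, wmh_pct_tiv = pct, log_wmh = log(pct))
}

# Shared guts for the OLS effect tests: returns the lm fit and checks input.
effect_lm <- function(formula, data, label) {
  fit <- stats::lm(formula, data = data)
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient design in ", label, "; aliased: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  fit
}

#' ANCOVA of pattern expression across blood pressure groups
#'
#' OLS of subject scores on blood pressure group (unordered factor) plus
#' nuisance covariates (age, sex, education, crystallized ability Gc).  The
#' group main effect F comes from the nested-model comparison against the
#' covariates-only fit; pairwise group contrasts (differences of adjusted
#' means, uncorrected — as customarily reported after a significant omnibus
#' F) are returned alongside.
#'
#' @param scores numeric subject scores.
#' @param bp_group factor (ordered or not) of group membership; subjects
#'   with `NA` or `"unclassified"` are dropped.
#' @param covariates data.frame of nuisance covariates (default columns
#'   `age`, `sex`, `low_education`, `gc_z`; any set of columns works).
#' @return List with `effect = "bp_group"`, `f_stat`, `dof` (numerator,
#'   denominator), `p`, `adj_r2` (of the full model), and `contrasts`
#'   (data.frame: comparison, estimate, se, t, p).
#' @export
ancova_group_effect <- function(scores, bp_group, covariates) {
  g <- droplevels(factor(bp_group, ordered = FALSE,
                         exclude = c(NA, "unclassified")))
  keep <- !is.na(g)
  if (anyNA(covariates[keep, , drop = FALSE]))
    stop("covariates must be complete for classified subjects")
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (any(table(g) < 3L)) stop("each group needs at least 3 subjects")
  dat <- data.frame(.scores = scores, .group = g, covariates,
                    check.names = TRUE)[keep, , drop = FALSE]
  cov_terms <- paste(setdiff(names(dat), c(".scores", ".group")),
                     collapse = " + ")
  full <- effect_lm(stats::as.formula(
    paste(".scores ~ .group +", cov_terms)), dat, "ANCOVA")
  null <- stats::lm(stats::as.formula(
    paste(".scores ~", cov_terms)), data = dat)
  an <- stats::anova(null, full)
  f <- an$F[2]; df1 <- an$Df[2]; df2 <- an$Res.Df[2]
  p <- an$`Pr(>F)`[2]

  # pairwise adjusted-mean contrasts from the full-model coefficients
  lev <- levels(dat$.group)
  cf <- stats::coef(full); V <- stats::vcov(full)
  coef_of <- function(l) {
    nm <- paste0(".group", l)
    v <- numeric(length(cf)); names(v) <- names(cf)
    if (nm %in% names(cf)) v[nm] <- 1
    v
  }
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  ctr <- do.call(rbind, lapply(pairs, function(pr) {
    cvec <- coef_of(pr[2]) - coef_of(pr[1])
    est <- sum(cvec * cf); se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    tt <- est / se
    data.frame(comparison = paste(pr[2], "-", pr[1]),
               estimate = est, se = se, t = tt,
               p = 2 * stats::pt(-abs(tt), df = full$df.residual))
  }))
  list(effect = "bp_group", f_stat = f, dof = c(df1, df2), p = p,
       adj_r2 = summary(full)$adj.r.squared, contrasts = ctr,
       n = nrow(dat))
}

#' Ordinal trend of pattern expression across ordered BP groups
#'
#' Linear ("ordinal") regression of standardized subject scores on the
#' ordered group code (normotensive = 0, controlled = 1, uncontrolled = 2),
#' covarying for age and education.  The reported `B` is the slope on the
#' group code with the response standardized; `adj_r2` and the two-tailed
#' `p` refer to the same model.
#'
#' @param scores numeric subject scores (standardized internally).
#' @param bp_group ordered factor or numeric code 0/1/2; unclassified /
#'   `NA` subjects are dropped.
#' @param covariates data.frame of covariates (default use: `age`,
#'   `low_education`).
#' @return List with `effect = "bp_trend"`, `beta`, `se`, `t`, `p`,
#'   `adj_r2`, `n`.
#' @export
ordinal_trend_test <- function(scores, bp_group, covariates) {
  if (is.numeric(bp_group)) {
    code <- bp_group
  } else {
    g <- factor(bp_group, exclude = c(NA, "unclassified"))
    code <- as.numeric(factor(as.character(g),
                              levels = c("normotensive", "controlled",
                                         "uncontrolled"))) - 1
  }
  keep <- !is.na(code)
  if (length(unique(code[keep])) < 2L)
    stop("all subjects in one group; no trend to test")
  z <- scores
  s <- stats::sd(z[keep])
  if (s < 1e-12) {
    # constant scores: slope is exactly 0 by construction
    return(list(effect = "bp_trend", beta = 0, se = NA_real_, t = NA_real_,
                p = 1, adj_r2 = NA_real_, n = sum(keep)))
  }
  z <- (z - mean(z[keep])) / s
  dat <- data.frame(.z = z, .code = code, covariates,
                    check.names = TRUE)[keep, , drop = FALSE]
  rhs <- paste(c(".code", setdiff(names(dat), c(".z", ".code"))),
               collapse = " + ")
  fit <- effect_lm(stats::as.formula(paste(".z ~", rhs)), dat,
                   "ordinal trend model")
  sm <- summary(fit)
  co <- sm$coefficients[".code", ]
  list(effect = "bp_trend", beta = unname(co["Estimate"]),
       se = unname(co["Std. Error"]), t = unname(co["t value"]),
       p = unname(co["Pr(>|t|)"]), adj_r2 = sm$adj.r.squared,
       n = nrow(dat))
}

#' Association between pattern expression and a cognitive domain
#'
#' OLS of a cognitive domain Z-score on the subject scores, controlling for
#' age and education.  `B` is the coefficient on the (standardized) subject
#' scores; with four domains tested, the Bonferroni-corrected p over the
#' four models is returned by [cognition_associations()].
#'
#' @param scores numeric subject scores.
#' @param domain_z numeric cognitive domain Z-scores.
#' @param covariates data.frame of covariates (`age`, `low_education`).
#' @param m number of models in the Bonferroni family (`NULL` for none).
#' @param domain label for the output.
#' @return List with `effect`, `beta`, `se`, `t`, `p`, `p_corrected`,
#'   `adj_r2`, `n`.
#' @export
cognition_association <- function(scores, domain_z, covariates,
                                  m = NULL, domain = "domain") {
  dat <- data.frame(.z = domain_z, .scores = scores, covariates,
                    check.names = TRUE)
  if (anyNA(dat)) stop("scores, domain_z and covariates must be complete")
  rhs <- paste(c(".scores", setdiff(names(dat), c(".z", ".scores"))),
               collapse = " + ")
  fit <- effect_lm(stats::as.formula(paste(".z ~", rhs)), dat,
                   "cognition model")
  sm <- summary(fit)
  co <- sm$coefficients[".scores", ]
  p <- unname(co["Pr(>|t|)"])
  list(effect = domain, beta = unname(co["Estimate"]),
       se = unname(co["Std. Error"]), t = unname(co["t value"]),
       p = p,
       p_corrected = if (is.null(m)) NA_real_ else bonferroni_correct(p, m),
       adj_r2 = sm$adj.r.squared, n = nrow(dat))
}

#' All four cognitive domain models with Bonferroni correction
#'
#' Runs [cognition_association()] for memory, executive function,
#' processing speed and language, applying a conservative Bonferroni
#' correction across the four models.
#'
#' @param scores numeric subject scores.
#' @param covariates covariate table containing `memory_z`, `exec_z`,
#'   `speed_z`, `language_z` plus the adjustment columns.
#' @param adjust_for columns used as covariates (default age, education).
#' @return data.frame with one row per domain: beta, p, p_corrected, adj_r2.
#' @export
cognition_associations <- function(scores, covariates,
                                   adjust_for = c("age", "low_education")) {
  domains <- c(memory = "memory_z", executive = "exec_z",
               speed = "speed_z", language = "language_z")
  adj <- covariates[, adjust_for, drop = FALSE]
  out <- lapply(names(domains), function(d) {
    r <- cognition_association(scores, covariates[[domains[[d]]]], adj,
                               m = length(domains), domain = d)
    data.frame(domain = d, beta = r$beta, se = r$se, t = r$t,
               p = r$p, p_corrected = r$p_corrected, adj_r2 = r$adj_r2)
  })
  do.call(rbind, out)
}

#' Bonferroni correction
#'
#' `min(1, m * p)` — the conservative correction applied over a family of
#' `m` models.
#'
#' @param p p-value in \[0, 1\].
#' @param m family size (>= 1).
#' @return Corrected p-value, vectorized over `p`.
#' @export
bonferroni_correct <- function(p, m) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must lie in [0, 1]")
  if (m < 1) stop("m must be >= 1")
  pmin(1, m * p)
}
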