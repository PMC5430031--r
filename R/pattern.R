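#' Akaike Information Criterion for a least-squares fit
#'
#' `AIC = n * ln(rss / n) + 2 * (k + 1)`, where `k` counts predictors
#' excluding the intercept (the `+ 1` counts the intercept).  With
#' `use_aicc = TRUE` the small-sample correction
#' `AICc = AIC + 2 (k + 1)(k + 2) / (n - k - 2)` is added.
#'
#' @param rss residual sum of squares (> 0; a numerically perfect fit must
#'   be handled by the caller, e.g. as a `-Inf` sentinel).
#' @param n number of observations (`n > k + 2`).
#' @param k number of predictors excluding the intercept.
#' @param use_aicc apply the small-sample correction.
#' @return The criterion value.
#' @export
aic_score <- function(rss, n, k, use_aicc = FALSE) {
  if (rss <= 0) stop("rss must be > 0 (perfect fits are the caller's job)")
  if (n <= k + 2) stop("need n > k + 2")
  aic <- n * log(rss / n) + 2 * (k + 1)
  if (use_aicc) aic <- aic + 2 * (k + 1) * (k + 2) / (n - k - 2)
  aic
}

# OLS by QR on an explicit design; returns coefficients and rss.
# Errors when the design is numerically rank deficient.
ols_fit <- function(X, y, label = "design") {
  kap <- kappa(X, exact = FALSE)
  if (!is.finite(kap) || kap > 1e10)
    stop("ill-conditioned ", label, " (condition number ", format(kap), ")")
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X))
    stop("rank-deficient ", label)
  beta <- qr.coef(qr_x, y)
  res <- y - X %*% beta
  list(beta = as.numeric(beta), rss = sum(res^2), fitted = as.numeric(X %*% beta))
}

#' Exhaustive AIC selection of the WMH-predicting component subset
#'
#' Evaluates every non-empty subset of the first `k_max` components with at
#' most `max_subset` members.  For each subset, log WMH burden is regressed
#' by ordinary least squares on an intercept, the subset's subject score
#' factors, and total intracranial volume (TIV) as a head-size covariate.
#' The subset with the lowest AIC wins; ties go to the smaller subset, then
#' to the lexicographically smallest index set.  Subsets need not be
#' contiguous — a winning set such as \{1, 2, 6\} is perfectly admissible.
#'
#' A numerically perfect fit (relative RSS below `perfect_tol`) is treated
#' as AIC `-Inf`, so noiseless constructions resolve deterministically.
#'
#' @param dec an `"ssm_decomposition"`.
#' @param y numeric response (log WMH), one value per subject.
#' @param tiv numeric TIV covariate, one value per subject.
#' @param k_max number of leading components searched (default 8).
#' @param max_subset largest subset size (default 4).
#' @param use_aicc use the small-sample AIC correction.
#' @param perfect_tol relative RSS below which a fit counts as perfect.
#' @return List with `selected` (integer indices), `betas` (named:
#'   intercept, `comp<i>`..., `tiv`), `aic`, `rss`, per-candidate table
#'   `candidates` (subset, size, aic, rss), and fit statistics `r`, `r2`,
#'   `adj_r2`, `r2_components` (subset fit without the TIV covariate),
#'   `n`, `k`.
#' @export
select_pattern <- function(dec, y, tiv, k_max = 8L, max_subset = 4L,
                           use_aicc = FALSE, perfect_tol = 1e-12) {
  stopifnot(inherits(dec, "ssm_decomposition"))
  # components with numerically zero variance carry no signal and would only
  # produce singular designs, so the search stops at the effective rank
  k_eff <- sum(dec$eigenvalues > 1e-12 * dec$eigenvalues[1])
  k_max <- min(as.integer(k_max), ncol(dec$ssf), k_eff)
  max_subset <- min(as.integer(max_subset), k_max)
  n <- length(y)
  if (n != nrow(dec$ssf) || length(tiv) != n)
    stop("y and tiv must align with the decomposition's subjects")
  tss <- sum((y - mean(y))^2)

  best <- NULL
  cand_subset <- character(0); cand_size <- integer(0)
  cand_aic <- numeric(0); cand_rss <- numeric(0)
  for (size in seq_len(max_subset)) {
    sets <- utils::combn(k_max, size, simplify = FALSE)
    for (S in sets) {
      X <- cbind(1, dec$ssf[, S, drop = FALSE], tiv)
      fit <- ols_fit(X, y, label = paste0(
        "design for subset {", paste(S, collapse = ","), "}"))
      k <- size + 1L   # components + TIV
      aic <- if (fit$rss <= perfect_tol * max(tss, 1)) -Inf
             else aic_score(fit$rss, n, k, use_aicc)
      cand_subset <- c(cand_subset, paste(S, collapse = ","))
      cand_size <- c(cand_size, size)
      cand_aic <- c(cand_aic, aic); cand_rss <- c(cand_rss, fit$rss)
      # strict improvement keeps the first (smallest, lexicographically
      # earliest) subset on ties, since sizes ascend and combn is lexicographic
      if (is.null(best) || aic < best$aic - 1e-9) {
        best <- list(S = S, aic = aic, fit = fit, k = k)
      }
    }
  }
  S <- best$S
  r2 <- 1 - best$fit$rss / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - best$k - 1)
  # subset fit without TIV, for reporting
  fit_nc <- ols_fit(cbind(1, dec$ssf[, S, drop = FALSE]), y,
                    label = "components-only design")
  betas <- best$fit$beta
  names(betas) <- c("intercept", paste0("comp", S), "tiv")
  list(selected = S, betas = betas, aic = best$aic, rss = best$fit$rss,
       fitted = best$fit$fitted,
       r = sqrt(max(0, r2)), r2 = r2, adj_r2 = adj_r2,
       r2_components = 1 - fit_nc$rss / tss,
       n = n, k = best$k,
       candidates = data.frame(subset = cand_subset, size = cand_size,
                               aic = cand_aic, rss = cand_rss))
}

#' Compose a voxel pattern from selected component loadings
#'
#' The composite WMH-related GMV pattern is the beta-weighted sum of the
#' selected components' voxel loadings.
#'
#' @param dec an `"ssm_decomposition"`.
#' @param selected integer component indices.
#' @param betas one regression coefficient per selected component.
#' @return Numeric voxel vector `sum_i betas[i] * loadings[selected[i], ]`.
#' @export
compose_pattern <- function(dec, selected, betas) {
  stopifnot(inherits(dec, "ssm_decomposition"))
  selected <- as.integer(selected)
  if (length(betas) != length(selected))
    stop("need one beta per selected component")
  if (any(selected < 1L | selected > nrow(dec$loadings)))
    stop("component index out of range")
  as.numeric(crossprod(dec$loadings[selected, , drop = FALSE], betas))
}

#' Subject expression scores of a voxel pattern
#'
#' Each subject's raw score is the inner product of their double-centered
#' log-GMV profile with the pattern weights; this measures how strongly the
#' subject expresses the pattern.  Scores are standardized to mean 0, SD 1
#' by default (group comparisons downstream are scale-free).
#'
#' @param dec an `"ssm_decomposition"` (its `centered` matrix is used).
#' @param pattern_weights numeric voxel vector.
#' @param standardize standardize the scores (default `TRUE`).
#' @return Numeric vector of subject scores.
#' @export
compute_subject_scores <- function(dec, pattern_weights, standardize = TRUE) {
  stopifnot(inherits(dec, "ssm_decomposition"))
  if (length(pattern_weights) != dec$n_voxels)
    stop("pattern length must equal the number of voxels")
  raw <- as.numeric(dec$centered %*% pattern_weights)
  if (!standardize) return(raw)
  s <- stats::sd(raw)
  if (!is.finite(s) || s < 1e-12)
    stop("degenerate score variance; cannot standardize a zero pattern")
  (raw - mean(raw)) / s
}

#' Fit the WMH-related gray matter covariance pattern
#'
#' The central model fit: runs the Scaled Subprofile Model on a gray matter
#' volume dataset (log transform, double-centering, PCA), selects by
#' exhaustive AIC search the subset of covariance components whose subject
#' score factors, together with intracranial volume, best predict log WMH
#' burden, composes the corresponding voxel pattern, and standardizes the
#' per-subject pattern expression scores.
#'
#' @param gmv a [gmv_matrix] (or plain subjects x voxels matrix).
#' @param covariates optional covariate table supplying `log_wmh` and
#'   `tiv_cc` columns (rows matched to the GMV subjects by position after
#'   checking ids when available).
#' @param log_wmh,tiv numeric vectors overriding / replacing the covariate
#'   columns.
#' @param k_max,max_subset,use_aicc see [select_pattern()].
#' @param offset_policy,epsilon see [log_transform()].
#' @return Object of class `"ssm_pattern"` with elements `decomposition`,
#'   `selected`, `betas`, `pattern_weights`, `subject_scores` (standardized),
#'   `raw_scores`, `fitted`, `y`, `tiv`, fit statistics (`r`, `r2`,
#'   `adj_r2`, `r2_components`, `aic`, `n`, `k`), the candidate table, and
#'   the call.
#' @examples
#' ds <- simulate_cohort(synthetic_config(n_subjects = 24,
#'                                        grid_shape = c(10, 10, 10),
#'                                        seed = 1))
#' fit <- ssm_pattern(ds$gmv, ds$covariates, k_max = 4, max_subset = 2)
#' print(fit)
#' @export
ssm_pattern <- function(gmv, covariates = NULL, log_wmh = NULL, tiv = NULL,
                        k_max = 8L, max_subset = 4L, use_aicc = FALSE,
                        offset_policy = "strict", epsilon = NULL) {
  if (is.null(log_wmh)) {
    if (is.null(covariates$log_wmh) || anyNA(covariates$log_wmh))
      stop("log_wmh not supplied and not available in covariates ",
           "(run add_derived_covariates() first)")
    log_wmh <- covariates$log_wmh
  }
  if (is.null(tiv)) {
    if (is.null(covariates$tiv_cc)) stop("tiv not supplied")
    tiv <- covariates$tiv_cc
  }
  if (inherits(gmv, "gmv_matrix") && !is.null(covariates$id) &&
      !identical(as.character(covariates$id), gmv$subject_ids))
    stop("covariate ids do not match GMV subject ids")

  dec <- ssm_decompose(gmv, offset_policy = offset_policy, epsilon = epsilon)
  sel <- select_pattern(dec, log_wmh, tiv, k_max = k_max,
                        max_subset = max_subset, use_aicc = use_aicc)
  comp_betas <- sel$betas[paste0("comp", sel$selected)]
  w <- compose_pattern(dec, sel$selected, comp_betas)
  raw <- compute_subject_scores(dec, w, standardize = FALSE)
  scores <- (raw - mean(raw)) / stats::sd(raw)
  structure(
    list(decomposition = dec, selected = sel$selected, betas = sel$betas,
         pattern_weights = w, subject_scores = scores, raw_scores = raw,
         fitted = sel$fitted, y = log_wmh, tiv = tiv,
         r = sel$r, r2 = sel$r2, adj_r2 = sel$adj_r2,
         r2_components = sel$r2_components,
         aic = sel$aic, n = sel$n, k = sel$k,
         candidates = sel$candidates,
         config = list(k_max = k_max, max_subset = max_subset,
                       use_aicc = use_aicc, offset_policy = offset_policy),
         call = match.call()),
    class = "ssm_pattern")
}

#' @export
print.ssm_pattern <- function(x, ...) {
  cat("SSM WMH~GMV pattern model\n")
  cat("  components selected:", paste(x$selected, collapse = ", "),
      sprintf("(searched k_max = %d, subsets up to %d)\n",
              x$config$k_max, x$config$max_subset))
  cat(sprintf("  R = %.3f, adj R^2 = %.3f, AIC = %s, n = %d\n",
              x$r, x$adj_r2, format(round(x$aic, 2)), x$n))
  invisible(x)
}

#' @export
summary.ssm_pattern <- function(object, ...) {
  out <- list(
    selected = object$selected, betas = object$betas,
    r = object$r, r2 = object$r2, adj_r2 = object$adj_r2,
    r2_components = object$r2_components, aic = object$aic,
    n = object$n, k = object$k,
    score_range = range(object$subject_scores),
    n_candidates = nrow(object$candidates))
  class(out) <- "summary.ssm_pattern"
  out
}

#' @export
print.summary.ssm_pattern <- function(x, ...) {
  cat("SSM WMH~GMV pattern model\n\n")
  cat("Selected components:", paste(x$selected, collapse = ", "), "\n")
  cat("Coefficients (log WMH ~ intercept + SSF + TIV):\n")
  print(signif(x$betas, 4))
  cat(sprintf("\nFull model:       R = %.3f, R^2 = %.3f, adj R^2 = %.3f\n",
              x$r, x$r2, x$adj_r2))
  cat(sprintf("Components only:  R^2 = %.3f\n", x$r2_components))
  cat(sprintf("AIC = %s over %d candidate subsets; n = %d, k = %d\n",
              format(round(x$aic, 2)), x$n_candidates, x$n, x$k))
  invisible(x)
}

#' @export
coef.ssm_pattern <- function(object, ...) object$betas

#' @export
fitted.ssm_pattern <- function(object, ...) object$fitted

#' @export
residuals.ssm_pattern <- function(object, ...) object$y - object$fitted

#' Pattern expression scores for new subjects
#'
#' Projects new subjects' GMV profiles onto the fitted pattern.  Each new
#' profile is log transformed, centered with its own mean across voxels and
#' the *training* group mean voxel profile (plus the training grand mean),
#' then projected onto the pattern weights; raw scores are standardized with
#' the training raw-score mean and SD so that new and fitted scores share a
#' scale.
#'
#' @param object a fitted `"ssm_pattern"`.
#' @param newdata a [gmv_matrix] or matrix on the same voxel set; omitting
#'   it returns the training subject scores.
#' @param ... unused.
#' @return Numeric vector of standardized scores.
#' @export
predict.ssm_pattern <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$subject_scores)
  x <- if (inherits(newdata, "gmv_matrix")) newdata$data else as.matrix(newdata)
  dec <- object$decomposition
  if (ncol(x) != dec$n_voxels)
    stop("newdata voxel count does not match the fitted mask")
  lx <- log_transform(x, object$config$offset_policy)
  centered <- lx - rowMeans(lx)
  centered <- sweep(centered, 2L, dec$col_means) + dec$grand_mean
  raw <- as.numeric(centered %*% object$pattern_weights)
  (raw - mean(object$raw_scores)) / stats::sd(object$raw_scores)
}

#' Plot subject scores against log WMH burden
#'
#' Scatter of standardized pattern expression scores versus the log WMH
#' response, with the least-squares line — the usual way the pattern/burden
#' association is displayed.
#'
#' @param x a fitted `"ssm_pattern"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ssm_pattern <- function(x, ...) {
  graphics::plot(x$subject_scores, x$y,
                 xlab = "SSM subject score (standardized)",
                 ylab = "log WMH (% of TIV)", ...)
  graphics::abline(stats::lm(x$y ~ x$subject_scores), col = "firebrick")
  invisible(x)
}
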