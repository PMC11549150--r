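stratum_rules <- c("icp_gt_15", "icp_le_15", "icp_gt_iop", "icp_le_iop")

stratum_subset <- function(obs, stratum, icp_threshold = 15) {
  if ("included" %in% names(obs)) obs <- dplyr::filter(obs, .data$included)
  obs <- dplyr::filter(obs, is.finite(.data$icp_mmhg))
  switch(stratum,
    icp_gt_15 = dplyr::filter(obs, .data$icp_mmhg > icp_threshold),
    icp_le_15 = dplyr::filter(obs, .data$icp_mmhg <= icp_threshold),
    icp_gt_iop = dplyr::filter(obs, is.finite(.data$iop_mmhg),
                               .data$icp_mmhg > .data$iop_mmhg),
    icp_le_iop = dplyr::filter(obs, is.finite(.data$iop_mmhg),
                               .data$icp_mmhg <= .data$iop_mmhg),
    stop("unknown stratum: ", stratum)
  )
}

#' Random-intercept slope of A/V ratio on ICP within one stratum
#'
#' Fits the mixed-effect linear regression `av_ratio ~ icp_mmhg` with a
#' per-patient random intercept (REML) on the subset of observations selected
#' by the stratum rule: `icp_gt_15` / `icp_le_15` split at `icp_threshold`
#' (strictly greater vs inclusive), `icp_gt_iop` / `icp_le_iop` split each
#' observation against its session IOP (rows with missing IOP are excluded
#' from IOP strata only). The reported interval is the normal (Wald)
#' `slope +/- 1.96 * SE`, and the p-value the two-sided normal tail of
#' `slope / SE`, matching the published tables' arithmetic.
#'
#' @param obs Observation tibble (see [join_sessions()] or
#'   [generate_cohort()]).
#' @param stratum One of `"icp_gt_15"`, `"icp_le_15"`, `"icp_gt_iop"`,
#'   `"icp_le_iop"`.
#' @param icp_threshold Knot, mmHg (default 15).
#' @param conf_z Normal quantile for the CI (default 1.96).
#' @return Object of class `stratum_fit`: stratum, slope, se, ci95, p, n_obs,
#'   n_patients, and the underlying `lmerMod` as `$model`.
#' @export
fit_stratum <- function(obs, stratum = stratum_rules, icp_threshold = 15,
                        conf_z = 1.96) {
  stratum <- match.arg(stratum)
  sub <- stratum_subset(obs, stratum, icp_threshold)
  n_pat <- dplyr::n_distinct(sub$patient_id)
  if (n_pat < 2 || nrow(sub) < 3) {
    stop(sprintf(
      "stratum '%s' unfittable: %d patients, %d observations (need >= 2 and >= 3)",
      stratum, n_pat, nrow(sub)))
  }
  fit <- suppressMessages(lme4::lmer(
    av_ratio ~ icp_mmhg + (1 | patient_id), data = sub, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore")
  ))
  beta <- lme4::fixef(fit)[["icp_mmhg"]]
  se <- sqrt(as.matrix(stats::vcov(fit))["icp_mmhg", "icp_mmhg"])
  z <- beta / se
  structure(
    list(
      stratum = stratum,
      slope = beta,
      se = se,
      ci95 = c(beta - conf_z * se, beta + conf_z * se),
      p = 2 * stats::pnorm(-abs(z)),
      n_obs = nrow(sub),
      n_patients = n_pat,
      model = fit
    ),
    class = "stratum_fit"
  )
}

#' @export
print.stratum_fit <- function(x, ...) {
  cat(sprintf(
    "<stratum_fit %s> slope %.4f (SE %.4f), 95%% CI [%.4f; %.4f], p %s, n = %d (%d patients)\n",
    x$stratum, x$slope, x$se, x$ci95[1], x$ci95[2],
    format.pval(x$p, digits = 3), x$n_obs, x$n_patients))
  invisible(x)
}

as_slope_se <- function(fit) {
  if (inherits(fit, "stratum_fit")) {
    c(slope = fit$slope, se = fit$se)
  } else if (is.numeric(fit) && length(fit) == 2) {
    c(slope = unname(fit[1]), se = unname(fit[2]))
  } else if (is.list(fit) && all(c("slope", "se") %in% names(fit))) {
    c(slope = fit$slope, se = fit$se)
  } else {
    stop("expected a stratum_fit or c(slope, se)")
  }
}

#' Two-sample z (Wald) comparison of two stratum slopes
#'
#' For independently fitted strata the slope difference has pooled standard
#' error `sqrt(se1^2 + se2^2)`; the statistic `z = diff / se_diff` is referred
#' to the standard normal (two-sided), and the interval is
#' `diff +/- 1.96 * se_diff`. These identities hold exactly by construction.
#'
#' @param fit1,fit2 `stratum_fit` objects, or numeric `c(slope, se)` pairs
#'   (e.g. printed table values).
#' @param conf_z Normal quantile for the CI (default 1.96).
#' @return Object of class `slope_comparison`: diff, se_diff, ci95, z, p.
#' @examples
#' compare_slopes(c(-0.0658860, 0.0003005), c(-0.0054981, 0.0003393))
#' @export
compare_slopes <- function(fit1, fit2, conf_z = 1.96) {
  a <- as_slope_se(fit1); b <- as_slope_se(fit2)
  if (a[["se"]] == 0 && b[["se"]] == 0) {
    stop("both standard errors are zero: z statistic undefined")
  }
  diff <- a[["slope"]] - b[["slope"]]
  se_diff <- sqrt(a[["se"]]^2 + b[["se"]]^2)
  z <- diff / se_diff
  structure(
    list(
      diff = diff,
      se_diff = se_diff,
      ci95 = c(diff - conf_z * se_diff, diff + conf_z * se_diff),
      z = z,
      p = 2 * stats::pnorm(-abs(z))
    ),
    class = "slope_comparison"
  )
}

#' @export
print.slope_comparison <- function(x, ...) {
  cat(sprintf(
    "<slope_comparison> diff %.7f (SE %.7f), 95%% CI [%.7f; %.7f], z = %.1f, p %s\n",
    x$diff, x$se_diff, x$ci95[1], x$ci95[2], x$z,
    format.pval(x$p, digits = 3)))
  invisible(x)
}

#' Pooled mixed-model summary: ICC, R-squared, Wald F
#'
#' Fits the pooled random-intercept model on all included observations with
#' the piecewise-linear (linear-spline) fixed-effect structure the stratified
#' analysis assumes — `av_ratio ~ min(ICP, thr) + max(ICP - thr, 0)` with a
#' per-patient random intercept — and summarises it:
#' \itemize{
#'   \item ICC: between-patient intercept variance over total variance,
#'     \eqn{\sigma^2_b / (\sigma^2_b + \sigma^2_w)}, with a large-sample
#'     (Fisher) standard error based on the average cluster size;
#'   \item R-squared: squared Pearson correlation between conditional fitted
#'     values and observations (one of several mixed-model R-squared
#'     conventions; chosen to mirror "variance explained by the predicted
#'     values");
#'   \item F: the Wald statistic for the fixed slopes divided by their
#'     number.
#' }
#'
#' @param obs Observation tibble.
#' @param icp_threshold Spline knot, mmHg.
#' @return Object of class `av_model_summary`: icc, icc_se, icc_ci95,
#'   r_squared, f_stat, n_obs, n_patients, and the `lmerMod` as `$model`.
#' @export
model_summary <- function(obs, icp_threshold = 15) {
  if ("included" %in% names(obs)) obs <- dplyr::filter(obs, .data$included)
  obs <- dplyr::filter(obs, is.finite(.data$icp_mmhg))
  n_pat <- dplyr::n_distinct(obs$patient_id)
  if (n_pat < 2 || nrow(obs) < 4) stop("too few data for the pooled model")
  dat <- dplyr::mutate(
    obs,
    icp_below = pmin(.data$icp_mmhg, icp_threshold),
    icp_above = pmax(.data$icp_mmhg - icp_threshold, 0)
  )
  fit <- suppressMessages(lme4::lmer(
    av_ratio ~ icp_below + icp_above + (1 | patient_id), data = dat,
    REML = TRUE, control = lme4::lmerControl(check.conv.singular = "ignore")
  ))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_b <- vc$vcov[vc$grp == "patient_id"]
  var_w <- vc$vcov[vc$grp == "Residual"]
  icc <- var_b / (var_b + var_w)

  # Fisher's large-sample SE for the one-way random-effects ICC,
  # with the mean cluster size standing in for a balanced design.
  k <- nrow(dat) / n_pat
  icc_se <- sqrt(2 * (1 - icc)^2 * (1 + (k - 1) * icc)^2 /
                   (k * (k - 1) * (n_pat - 1)))
  icc_ci <- clip(icc + c(-1.96, 1.96) * icc_se, 0, 1)

  r2 <- stats::cor(stats::fitted(fit), dat$av_ratio)^2

  beta <- lme4::fixef(fit)[-1]
  V <- as.matrix(stats::vcov(fit))[-1, -1, drop = FALSE]
  f_stat <- as.numeric(t(beta) %*% solve(V, beta)) / length(beta)

  structure(
    list(
      icc = icc, icc_se = icc_se, icc_ci95 = icc_ci,
      r_squared = r2, f_stat = f_stat,
      n_obs = nrow(dat), n_patients = n_pat,
      model = fit
    ),
    class = "av_model_summary"
  )
}

#' @export
print.av_model_summary <- function(x, ...) {
  cat(sprintf(
    "<av_model_summary> ICC %.4f (SE %.3f, 95%% CI [%.3f; %.3f]), R^2 %.4f, F %.1f, n = %d (%d patients)\n",
    x$icc, x$icc_se, x$icc_ci95[1], x$icc_ci95[2], x$r_squared, x$f_stat,
    x$n_obs, x$n_patients))
  invisible(x)
}

#' Diagnostic accuracy of the A/V cut-off for elevated ICP
#'
#' Evaluates the A/V ratio as a screening test for ICP above
#' `icp_threshold` mmHg: a positive call is `av_ratio < cutoff` (a low A/V
#' ratio predicts elevated ICP). Reports the confusion matrix at the cut-off,
#' sensitivity, specificity, predictive values, and the
#' threshold-independent AUC (rank statistic with midranks for ties, via
#' pROC). The AUC is invariant to any strictly monotone transform of the A/V
#' ratio.
#'
#' @param obs Observation tibble with `av_ratio` and `icp_mmhg`.
#' @param cutoff A/V area-ratio cut-off (default 0.75).
#' @param icp_threshold Elevated-ICP definition, mmHg (default 15; strictly
#'   greater).
#' @return Object of class `av_diagnostics`: cutoff, sensitivity,
#'   specificity, ppv, npv, auc, confusion (tp, fp, tn, fn), n.
#' @export
diagnostics <- function(obs, cutoff = 0.75, icp_threshold = 15) {
  if ("included" %in% names(obs)) obs <- dplyr::filter(obs, .data$included)
  obs <- dplyr::filter(obs, is.finite(.data$icp_mmhg), is.finite(.data$av_ratio))
  truth <- obs$icp_mmhg > icp_threshold
  if (!any(truth) || all(truth)) {
    stop("diagnostics needs both ICP classes present")
  }
  call_pos <- obs$av_ratio < cutoff
  tp <- sum(call_pos & truth)
  fp <- sum(call_pos & !truth)
  tn <- sum(!call_pos & !truth)
  fn <- sum(!call_pos & truth)
  roc <- pROC::roc(response = truth, predictor = obs$av_ratio,
                   levels = c(FALSE, TRUE), direction = ">", quiet = TRUE)
  structure(
    list(
      cutoff = cutoff,
      sensitivity = tp / (tp + fn),
      specificity = tn / (tn + fp),
      ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
      auc = as.numeric(pROC::auc(roc)),
      confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
      n = nrow(obs)
    ),
    class = "av_diagnostics"
  )
}

#' @export
print.av_diagnostics <- function(x, ...) {
  cat(sprintf(
    "<av_diagnostics cutoff %.2f> sens %.1f%%, spec %.1f%%, PPV %.1f%%, NPV %.1f%%, AUC %.4f (n = %d)\n",
    x$cutoff, 100 * x$sensitivity, 100 * x$specificity, 100 * x$ppv,
    100 * x$npv, x$auc, x$n))
  invisible(x)
}

#' Negative predictive value implied by sensitivity, specificity and PPV
#'
#' Consistency check for printed diagnostic metrics: Bayes' rule gives
#' `PPV = sens * pi / (sens * pi + (1 - spec) * (1 - pi))` for prevalence
#' `pi`, which solves in closed form to
#' `pi = x / (1 + x)` with `x = PPV (1 - spec) / (sens (1 - PPV))`; the NPV
#' then follows as `spec (1 - pi) / (spec (1 - pi) + (1 - sens) pi)`. When a
#' total count is supplied the implied confusion matrix is returned as well.
#'
#' @param sens,spec,ppv Metrics in (0, 1] (proportions, not percent).
#' @param n_total Optional total observation count for the implied confusion
#'   matrix.
#' @return `list(prevalence, npv, confusion)` (`confusion` is `NULL` without
#'   `n_total`). Errors when no prevalence in (0, 1) is consistent with the
#'   inputs.
#' @examples
#' implied_npv(0.8008, 0.2251, 0.757, n_total = 7762)
#' @export
implied_npv <- function(sens, spec, ppv, n_total = NULL) {
  stopifnot(sens > 0, sens <= 1, spec >= 0, spec <= 1, ppv > 0, ppv <= 1)
  if (ppv == 1) {
    if (spec < 1) stop("PPV = 1 requires perfect specificity or prevalence 1")
    return(list(prevalence = NA_real_, npv = 1, confusion = NULL))
  }
  x <- ppv * (1 - spec) / (sens * (1 - ppv))
  prev <- x / (1 + x)
  if (!is.finite(prev) || prev <= 0 || prev >= 1) {
    stop("inputs are inconsistent: no prevalence in (0, 1) satisfies Bayes' rule")
  }
  npv <- spec * (1 - prev) / (spec * (1 - prev) + (1 - sens) * prev)
  confusion <- NULL
  if (!is.null(n_total)) {
    confusion <- c(
      tp = round(n_total * prev * sens),
      fp = round(n_total * (1 - prev) * (1 - spec)),
      tn = round(n_total * (1 - prev) * spec),
      fn = round(n_total * prev * (1 - sens))
    )
  }
  list(prevalence = prev, npv = npv, confusion = confusion)
}

#' Fit all four published strata at once
#'
#' Convenience wrapper running [fit_stratum()] for each stratum rule and
#' collecting the results in a table. Strata that cannot be fitted (e.g. IOP
#' strata when IOP is missing) are skipped with a warning.
#'
#' @param obs Observation tibble.
#' @param strata Stratum names (default all four).
#' @param icp_threshold Knot, mmHg.
#' @return Tibble with one row per fitted stratum: stratum, slope, se, ci_lo,
#'   ci_hi, p, n_obs, n_patients. The fit objects are attached as the
#'   `"fits"` attribute (a named list).
#' @export
fit_all_strata <- function(obs, strata = stratum_rules, icp_threshold = 15) {
  fits <- list()
  for (s in strata) {
    f <- tryCatch(fit_stratum(obs, s, icp_threshold),
                  error = function(e) {
                    warning(conditionMessage(e), call. = FALSE)
                    NULL
                  })
    if (!is.null(f)) fits[[s]] <- f
  }
  if (length(fits) == 0) stop("no stratum could be fitted")
  out <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(
      stratum = f$stratum, slope = f$slope, se = f$se,
      ci_lo = f$ci95[1], ci_hi = f$ci95[2], p = f$p,
      n_obs = f$n_obs, n_patients = f$n_patients
    )
  })
  attr(out, "fits") <- fits
  out
}
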