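#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a stratum fit
#'
#' @param x A `stratum_fit`.
#' @param ... Unused.
#' @return One-row tibble: stratum, term, estimate, std.error, conf.low,
#'   conf.high, statistic, p.value.
#' @export
tidy.stratum_fit <- function(x, ...) {
  tibble::tibble(
    stratum = x$stratum,
    term = "icp_mmhg",
    estimate = x$slope,
    std.error = x$se,
    conf.low = x$ci95[1],
    conf.high = x$ci95[2],
    statistic = x$slope / x$se,
    p.value = x$p
  )
}

#' @rdname tidy.stratum_fit
#' @export
glance.stratum_fit <- function(x, ...) {
  tibble::tibble(nobs = x$n_obs, n_patients = x$n_patients,
                 sigma = stats::sigma(x$model))
}

#' Tidy a slope comparison
#'
#' @param x A `slope_comparison`.
#' @param ... Unused.
#' @return One-row tibble: estimate (difference), std.error, conf.low,
#'   conf.high, statistic (z), p.value.
#' @export
tidy.slope_comparison <- function(x, ...) {
  tibble::tibble(
    estimate = x$diff,
    std.error = x$se_diff,
    conf.low = x$ci95[1],
    conf.high = x$ci95[2],
    statistic = x$z,
    p.value = x$p
  )
}

#' Tidy / glance a pooled model summary
#'
#' @param x An `av_model_summary`.
#' @param ... Unused.
#' @return `tidy()`: fixed-effect terms with estimates and SEs. `glance()`:
#'   one row with icc, icc_se, icc conf limits, r.squared, statistic (Wald F),
#'   nobs, n_patients.
#' @export
tidy.av_model_summary <- function(x, ...) {
  beta <- lme4::fixef(x$model)
  se <- sqrt(diag(as.matrix(stats::vcov(x$model))))
  tibble::tibble(term = names(beta), estimate = unname(beta),
                 std.error = unname(se))
}

#' @rdname tidy.av_model_summary
#' @export
glance.av_model_summary <- function(x, ...) {
  tibble::tibble(
    icc = x$icc, icc_se = x$icc_se,
    icc_conf.low = x$icc_ci95[1], icc_conf.high = x$icc_ci95[2],
    r.squared = x$r_squared, statistic = x$f_stat,
    nobs = x$n_obs, n_patients = x$n_patients
  )
}

#' Tidy / glance diagnostic results
#'
#' @param x An `av_diagnostics`.
#' @param ... Unused.
#' @return `tidy()`: one row per metric (sensitivity, specificity, ppv, npv,
#'   auc). `glance()`: one row with all metrics plus the confusion counts.
#' @export
tidy.av_diagnostics <- function(x, ...) {
  tibble::tibble(
    metric = c("sensitivity", "specificity", "ppv", "npv", "auc"),
    estimate = c(x$sensitivity, x$specificity, x$ppv, x$npv, x$auc)
  )
}

#' @rdname tidy.av_diagnostics
#' @export
glance.av_diagnostics <- function(x, ...) {
  tibble::tibble(
    cutoff = x$cutoff,
    sensitivity = x$sensitivity, specificity = x$specificity,
    ppv = x$ppv, npv = x$npv, auc = x$auc,
    tp = x$confusion[["tp"]], fp = x$confusion[["fp"]],
    tn = x$confusion[["tn"]], fn = x$confusion[["fn"]],
    nobs = x$n
  )
}
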