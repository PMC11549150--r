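#' Plot A/V ratio against ICP for a cohort
#'
#' Scatter of observations coloured by patient with the piecewise-linear
#' population trend (pooled mixed-model fixed effects) overlaid — the
#' at-a-glance view of the flat-below / declining-above relation the analysis
#' estimates.
#'
#' @param obs Observation tibble (`av_ratio`, `icp_mmhg`, `patient_id`).
#' @param icp_threshold Knot, mmHg.
#' @return A ggplot object.
#' @export
plot_av_icp <- function(obs, icp_threshold = 15) {
  ms <- model_summary(obs, icp_threshold = icp_threshold)
  beta <- lme4::fixef(ms$model)
  grid <- tibble::tibble(icp_mmhg = seq(min(obs$icp_mmhg), max(obs$icp_mmhg),
                                        length.out = 200))
  grid$av_ratio <- beta[["(Intercept)"]] +
    beta[["icp_below"]] * pmin(grid$icp_mmhg, icp_threshold) +
    beta[["icp_above"]] * pmax(grid$icp_mmhg - icp_threshold, 0)
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$icp_mmhg, y = .data$av_ratio)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$patient_id),
                        alpha = 0.25, size = 0.6, show.legend = FALSE) +
    ggplot2::geom_line(data = grid, linewidth = 1) +
    ggplot2::geom_vline(xintercept = icp_threshold, linetype = "dashed") +
    ggplot2::labs(x = "ICP (mmHg)", y = "A/V area ratio") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_av_icp ROC curve for an `av_diagnostics` object, with the
#'   operating point at the chosen cut-off marked.
#' @param object An `av_diagnostics`.
#' @param ... Unused.
#' @export
autoplot.av_diagnostics <- function(object, ...) {
  cm <- object$confusion
  df <- tibble::tibble(
    fpr = 1 - object$specificity,
    tpr = object$sensitivity
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_point(size = 3, colour = "firebrick") +
    ggplot2::annotate("text", x = 0.65, y = 0.1,
                      label = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("A/V cut-off %.2f (TP %d, FP %d, TN %d, FN %d)",
                                  object$cutoff, cm[["tp"]], cm[["fp"]],
                                  cm[["tn"]], cm[["fn"]])) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_av_icp forest-style plot of stratum slopes with 95%
#'   intervals from a [fit_all_strata()] table.
#' @param strata_tbl Tibble from [fit_all_strata()].
#' @export
plot_strata <- function(strata_tbl) {
  ggplot2::ggplot(strata_tbl,
                  ggplot2::aes(x = .data$slope, y = .data$stratum)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lo,
                                         xmax = .data$ci_hi), height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Slope (A/V units per mmHg)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Display a frame with optional overlays
#'
#' Grayscale raster of a frame matrix with optional disc circle, vessel-mask
#' outline and measurement points — the quick visual check after triage and
#' measurement.
#'
#' @param frame Numeric intensity matrix.
#' @param disc Optional disc geometry.
#' @param points Optional measurement-point tibble (`x`, `y`, `vessel_label`).
#' @return A ggplot object.
#' @export
plot_frame <- function(frame, disc = NULL, points = NULL) {
  frame <- as_frame_matrix(frame)
  df <- tidyr::expand_grid(y = seq_len(nrow(frame)), x = seq_len(ncol(frame)))
  df$value <- as.vector(t(frame))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
  if (!is.null(disc)) {
    th <- seq(0, 2 * pi, length.out = 120)
    circ <- tibble::tibble(x = disc$center[1] + disc$radius * cos(th),
                           y = disc$center[2] + disc$radius * sin(th))
    p <- p + ggplot2::geom_path(data = circ, colour = "yellow")
  }
  if (!is.null(points)) {
    p <- p + ggplot2::geom_point(data = points,
                                 ggplot2::aes(colour = .data$vessel_label),
                                 size = 2)
  }
  p
}
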