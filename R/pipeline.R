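#' Pipeline configuration
#'
#' One place for every tunable the pipeline uses; all defaults equal the
#' published constants (1.5x disc crop, 5 s ICP half-window, 15 mmHg ICP
#' threshold, 0.75 A/V cut-off, 128 px patches).
#'
#' @param frames_dir Directory of `frame_%06d.png` files plus `frames.csv`.
#' @param icp_csv ICP recording CSV (`timestamp_s`, `icp_mmhg`, optionally
#'   `session_id`).
#' @param iop_csv Per-session IOP CSV (`session_id`, `iop_mmhg`), or NULL.
#' @param out_dir Output directory.
#' @param crop_factor Disc-crop factor for quality scoring.
#' @param min_corr Alignment acceptance threshold.
#' @param n_points Measurement points per vessel.
#' @param patch_size Measurement patch side, pixels.
#' @param outlier_k Width-outlier threshold, scaled-MAD units.
#' @param profile_step Perpendicular sampling step, pixels.
#' @param window ICP averaging half-window, seconds.
#' @param icp_threshold Elevated-ICP knot, mmHg.
#' @param av_cutoff Diagnostic A/V cut-off.
#' @param measure_frames `"reference"` (measure the reference frame only) or
#'   `"included"` (every aligned fundus frame).
#' @param seed Seed for the simulation entry point.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(frames_dir = NULL, icp_csv = NULL, iop_csv = NULL,
                            out_dir = "retinaicp-out",
                            crop_factor = 1.5, min_corr = 0.3,
                            n_points = 3, patch_size = 128, outlier_k = 3,
                            profile_step = 0.1, window = 5,
                            icp_threshold = 15, av_cutoff = 0.75,
                            measure_frames = c("reference", "included"),
                            seed = 1L) {
  stopifnot(crop_factor > 0, min_corr >= 0, n_points >= 0, patch_size >= 16,
            outlier_k > 0, profile_step > 0, window > 0, icp_threshold > 0,
            av_cutoff > 0)
  structure(
    list(
      frames_dir = frames_dir, icp_csv = icp_csv, iop_csv = iop_csv,
      out_dir = out_dir, crop_factor = crop_factor, min_corr = min_corr,
      n_points = n_points, patch_size = patch_size, outlier_k = outlier_k,
      profile_step = profile_step, window = window,
      icp_threshold = icp_threshold, av_cutoff = av_cutoff,
      measure_frames = match.arg(measure_frames),
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Simulate a phantom session and a synthetic cohort
#'
#' Thin wrapper over the generators: renders a phantom frame sequence into
#' `<out_dir>/frames` (PNGs, `frames.csv`, ground-truth sidecar), writes a
#' matching constant-rate ICP recording and session IOP file, and a
#' synthetic hierarchical cohort CSV.
#'
#' @param config A [pipeline_config()].
#' @param phantom A [frame_phantom_spec()] (seed is taken from `config`).
#' @param cohort A [cohort_spec()] (seed taken from `config`).
#' @return Invisibly, a named list of the written paths.
#' @export
run_simulate <- function(config = pipeline_config(),
                         phantom = frame_phantom_spec(),
                         cohort = cohort_spec()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  phantom$seed <- config$seed
  cohort$seed <- config$seed

  frames_dir <- file.path(config$out_dir, "frames")
  stack <- render_frames(phantom)
  write_frames(stack, frames_dir)

  set.seed(config$seed)
  t_max <- max(stack$info$timestamp_s) + config$window
  icp <- tibble::tibble(
    timestamp_s = seq(0, t_max, by = 0.5),
    icp_mmhg = round(stats::rnorm(1, cohort$icp_mean, cohort$icp_sd), 1)
  )
  icp_path <- file.path(config$out_dir, "icp.csv")
  readr::write_csv(icp, icp_path)
  iop <- tibble::tibble(
    session_id = "S01",
    iop_mmhg = round(clip(stats::rnorm(1, cohort$iop_mean, cohort$iop_sd),
                          cohort$iop_range[1], cohort$iop_range[2]), 1)
  )
  iop_path <- file.path(config$out_dir, "iop.csv")
  readr::write_csv(iop, iop_path)

  coh <- generate_cohort(cohort)
  cohort_path <- file.path(config$out_dir, "cohort.csv")
  write_cohort_csv(coh, cohort_path)

  invisible(list(frames_dir = frames_dir, icp_csv = icp_path,
                 iop_csv = iop_path, cohort_csv = cohort_path))
}

#' Measure A/V ratios from a frame directory
#'
#' The measurement stage: reads the frame directory, triages and aligns
#' frames, selects the reference, measures per-point vessel widths and A/V
#' ratios on the configured frames, and writes `triage.csv` (per-frame class,
#' quality, shift, inclusion and reason) and `measurements.csv` (per point:
#' frame timestamp, vessel label, mean width, line counts) plus
#' `av_ratios.csv` (per point pair). Errors when no usable fundus frame
#' exists (`excluded: image quality`).
#'
#' @param config A [pipeline_config()] with `frames_dir` set.
#' @return Invisibly, `list(triage, measurements, av_ratios)` tibbles.
#' @export
run_measure <- function(config) {
  stopifnot(inherits(config, "pipeline_config"), !is.null(config$frames_dir))
  if (!dir.exists(config$frames_dir) ||
      !file.exists(file.path(config$frames_dir, "frames.csv"))) {
    stop("frames_dir does not exist or lacks frames.csv")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stack <- read_frames(config$frames_dir)

  tri <- tryCatch(
    triage_frames(stack, min_corr = config$min_corr,
                  crop_factor = config$crop_factor),
    error = function(e) stop("excluded: image quality (", conditionMessage(e), ")")
  )
  readr::write_csv(tri$report, file.path(config$out_dir, "triage.csv"))

  idx <- if (config$measure_frames == "reference") {
    tri$reference
  } else {
    tri$report$frame_index[tri$report$included]
  }
  truth_labels <- if (!is.null(stack$truth)) stack$truth$centerlines else NULL

  meas <- list(); avs <- list()
  for (i in idx) {
    res <- tryCatch(
      measure_frame(stack$frames[[i]], n_points = config$n_points,
                    truth_labels = truth_labels,
                    patch_size = config$patch_size,
                    outlier_k = config$outlier_k,
                    step = config$profile_step),
      error = function(e) NULL
    )
    if (is.null(res)) next
    pts <- res$points
    pts$frame_index <- i
    pts$timestamp_s <- stack$info$timestamp_s[stack$info$frame_index == i]
    meas[[length(meas) + 1]] <- pts
    if (!is.null(res$pairs)) {
      pr <- res$pairs
      pr$frame_index <- i
      pr$timestamp_s <- stack$info$timestamp_s[stack$info$frame_index == i]
      avs[[length(avs) + 1]] <- pr
    }
  }
  if (length(meas) == 0) stop("excluded: image quality (no measurable frames)")
  measurements <- dplyr::bind_rows(meas)
  av_ratios <- dplyr::bind_rows(avs)
  readr::write_csv(measurements, file.path(config$out_dir, "measurements.csv"))
  readr::write_csv(av_ratios, file.path(config$out_dir, "av_ratios.csv"))
  invisible(list(triage = tri$report, measurements = measurements,
                 av_ratios = av_ratios))
}

#' Run the statistical analysis stage
#'
#' Reads a joined observation CSV (the synthetic-cohort schema), fits the
#' four published strata, compares the ICP > 15 mmHg slope with the
#' ICP > IOP slope by a two-sample z test, summarises the pooled model (ICC,
#' R-squared, F), and evaluates the diagnostic cut-off. Writes
#' `strata.csv`, `slope_comparison.csv` and `results.json`.
#'
#' @param config A [pipeline_config()].
#' @param observations_csv Path to the observation CSV (defaults to
#'   `<out_dir>/cohort.csv` as written by [run_simulate()]).
#' @return Invisibly, `list(strata, comparison, summary, diagnostics)`.
#' @export
run_analyze <- function(config, observations_csv = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  path <- observations_csv %||% file.path(config$out_dir, "cohort.csv")
  if (!file.exists(path)) stop("observation CSV not found: ", path)
  obs <- read_cohort_csv(path)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  have_iop <- "iop_mmhg" %in% names(obs) && any(is.finite(obs$iop_mmhg))
  strata <- if (have_iop) stratum_rules else c("icp_gt_15", "icp_le_15")
  if (!have_iop) warning("no IOP values: IOP strata skipped")
  tab <- fit_all_strata(obs, strata = strata,
                        icp_threshold = config$icp_threshold)
  readr::write_csv(tab, file.path(config$out_dir, "strata.csv"))

  fits <- attr(tab, "fits")
  cmp <- NULL
  if (all(c("icp_gt_15", "icp_gt_iop") %in% names(fits))) {
    cmp <- compare_slopes(fits$icp_gt_15, fits$icp_gt_iop)
    readr::write_csv(tidy(cmp), file.path(config$out_dir, "slope_comparison.csv"))
  }
  ms <- model_summary(obs, icp_threshold = config$icp_threshold)
  dg <- tryCatch(
    diagnostics(obs, cutoff = config$av_cutoff,
                icp_threshold = config$icp_threshold),
    error = function(e) {
      warning("diagnostics skipped: ", conditionMessage(e))
      NULL
    }
  )

  results <- list(
    strata = tab,
    slope_comparison = if (!is.null(cmp)) tidy(cmp),
    model = glance(ms),
    diagnostics = if (!is.null(dg)) glance(dg)
  )
  jsonlite::write_json(results, file.path(config$out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(strata = tab, comparison = cmp, summary = ms,
                 diagnostics = dg))
}

#' Run simulate, measure and analyze end to end
#'
#' @param config A [pipeline_config()].
#' @param ... Passed to [run_simulate()].
#' @return Invisibly, the [run_analyze()] result.
#' @export
run_all <- function(config = pipeline_config(), ...) {
  paths <- run_simulate(config, ...)
  cfg <- config
  cfg$frames_dir <- paths$frames_dir
  run_measure(cfg)
  run_analyze(cfg, observations_csv = paths$cohort_csv)
}
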