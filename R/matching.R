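#' Window-averaged ICP at a frame timestamp
#'
#' The reference ICP attached to an A/V observation is the arithmetic mean of
#' all recorded ICP samples with timestamps in the closed interval
#' `[t - window, t + window]` (default 5 s each side — samples exactly on the
#' boundary are included). No interpolation is performed: only observed
#' samples are averaged. An empty window yields `NA` with `n_samples = 0`;
#' the observation is then excluded, not imputed.
#'
#' @param series Tibble/data frame with columns `timestamp_s` (strictly
#'   increasing) and `icp_mmhg` (finite; negative ICP is allowed).
#' @param t Frame timestamp(s), seconds (vectorised).
#' @param window Half-window, seconds (default 5).
#' @return Tibble with one row per `t`: `timestamp_s`, `icp_mmhg`
#'   (window mean, `NA` when empty), `n_icp_samples`.
#' @examples
#' s <- tibble::tibble(timestamp_s = c(6, 10, 14), icp_mmhg = c(10, 12, 14))
#' window_mean_icp(s, 10)  # mean of all three samples = 12
#' @export
window_mean_icp <- function(series, t, window = 5) {
  stopifnot(nrow(series) > 0, window > 0)
  ts <- series$timestamp_s
  if (is.unsorted(ts, strictly = TRUE)) {
    o <- order(ts)
    ts <- ts[o]
    series <- series[o, ]
    if (anyDuplicated(ts)) stop("ICP timestamps must be strictly increasing")
  }
  cs <- c(0, cumsum(series$icp_mmhg))
  lo <- findInterval(t - window, ts, left.open = TRUE)   # samples strictly before t - window
  hi <- findInterval(t + window, ts)                     # samples at or before t + window
  n <- hi - lo
  total <- ifelse(n > 0, cs[hi + 1] - cs[lo + 1], NA_real_)
  tibble::tibble(
    timestamp_s = t,
    icp_mmhg = total / n,
    n_icp_samples = as.integer(pmax(n, 0))
  )
}

#' Join A/V measurements to windowed ICP and session IOP
#'
#' Builds the analysis table: each per-frame A/V measurement is joined to the
#' window-mean ICP of its session's ICP recording and to the session's IOP.
#' Rows with an empty ICP window are flagged excluded (never imputed); rows
#' from sessions without an IOP value keep `iop_mmhg = NA` and are excluded
#' from IOP-stratified analyses only. An exclusion log is attached as the
#' `"exclusions"` attribute.
#'
#' @param av_table Tibble with columns `patient_id`, `session_id`,
#'   `timestamp_s`, `av_ratio`.
#' @param icp_series Tibble with columns `session_id`, `timestamp_s`,
#'   `icp_mmhg` (one recording per session), or a single-session tibble
#'   without `session_id` when `av_table` has one session.
#' @param iop_table Tibble with columns `session_id`, `iop_mmhg`, or NULL.
#' @param window Half-window, seconds.
#' @return Tibble of observations: `patient_id`, `session_id`, `timestamp_s`,
#'   `av_ratio`, `icp_mmhg`, `iop_mmhg`, `n_icp_samples`, `included`.
#' @export
join_sessions <- function(av_table, icp_series, iop_table = NULL, window = 5) {
  stopifnot(all(c("patient_id", "session_id", "timestamp_s", "av_ratio")
                %in% names(av_table)))
  if (!"session_id" %in% names(icp_series)) {
    sess <- unique(av_table$session_id)
    if (length(sess) != 1) {
      stop("icp_series lacks session_id but av_table has multiple sessions")
    }
    icp_series$session_id <- sess
  }

  joined <- av_table |>
    dplyr::group_by(.data$session_id) |>
    dplyr::group_modify(function(df, key) {
      s <- dplyr::filter(icp_series, .data$session_id == key$session_id)
      if (nrow(s) == 0) {
        df$icp_mmhg <- NA_real_
        df$n_icp_samples <- 0L
        return(df)
      }
      wm <- window_mean_icp(s, df$timestamp_s, window = window)
      df$icp_mmhg <- wm$icp_mmhg
      df$n_icp_samples <- wm$n_icp_samples
      df
    }) |>
    dplyr::ungroup()

  if (!is.null(iop_table)) {
    joined <- dplyr::left_join(
      joined, dplyr::select(iop_table, "session_id", "iop_mmhg"),
      by = "session_id"
    )
  } else {
    joined$iop_mmhg <- NA_real_
  }
  joined$included <- joined$n_icp_samples >= 1

  excl <- dplyr::filter(joined, !.data$included)
  out <- dplyr::select(
    joined, "patient_id", "session_id", "timestamp_s", "av_ratio",
    "icp_mmhg", "iop_mmhg", "n_icp_samples", "included"
  )
  attr(out, "exclusions") <- tibble::tibble(
    session_id = excl$session_id,
    timestamp_s = excl$timestamp_s,
    reason = rep("no ICP samples in window", nrow(excl))
  )
  out
}
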