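#' Detect the optic disc as a bright circular blob
#'
#' Classical stand-in for an object detector: the frame is Gaussian-smoothed,
#' the brightest pixel located, and the connected region above half the peak
#' prominence (relative to the median background) taken as the disc. The
#' half-level set of a blurred disc sits at the original disc edge, so the
#' region centroid and equivalent-circle radius estimate the disc centre and
#' radius. Returns `NULL` when the peak prominence is below threshold or the
#' disc is not fully inside the frame — a `NULL` return is the only failure
#' signal.
#'
#' @param frame Numeric matrix (rows = y, cols = x), intensities in [0, 1].
#' @param smooth_sigma Gaussian smoothing SD, pixels.
#' @param min_prominence Minimum peak-minus-median intensity for a disc call.
#' @param min_radius Smallest plausible disc radius, pixels.
#' @param border_margin Disc must clear the frame border by this many pixels.
#' @return `list(center = c(x, y), radius = r)` or `NULL`.
#' @export
detect_disc <- function(frame, smooth_sigma = 5, min_prominence = 0.08,
                        min_radius = 6, border_margin = 2) {
  frame <- as_frame_matrix(frame)
  if (nrow(frame) < 16 || ncol(frame) < 16) return(NULL)
  sm <- EBImage::gblur(frame, sigma = smooth_sigma)
  bg <- stats::median(sm)
  peak <- max(sm)
  if (peak - bg < min_prominence) return(NULL)

  mask <- sm >= bg + 0.5 * (peak - bg)
  lab <- EBImage::bwlabel(mask)
  peak_idx <- which.max(sm)
  id <- lab[peak_idx]
  if (id == 0) return(NULL)
  sel <- lab == id
  ys <- row(sel)[sel]; xs <- col(sel)[sel]
  cx <- mean(xs); cy <- mean(ys)
  radius <- sqrt(sum(sel) / pi)
  if (radius < min_radius) return(NULL)
  if (min(xs) <= border_margin || min(ys) <= border_margin ||
      max(xs) > ncol(frame) - border_margin ||
      max(ys) > nrow(frame) - border_margin) {
    return(NULL)  # disc truncated by the frame border
  }
  list(center = c(cx, cy), radius = radius)
}

# Square crop of side crop_factor * (2 * radius), centred on the disc and
# clamped to the frame.
disc_crop <- function(frame, disc, crop_factor = 1.5) {
  side <- round(crop_factor * 2 * disc$radius)
  half <- floor(side / 2)
  cx <- round(disc$center[1]); cy <- round(disc$center[2])
  x0 <- max(1, cx - half); x1 <- min(ncol(frame), cx + half)
  y0 <- max(1, cy - half); y1 <- min(nrow(frame), cy + half)
  frame[y0:y1, x0:x1, drop = FALSE]
}

sobel_gradients <- function(img) {
  h <- nrow(img); w <- ncol(img)
  if (h < 3 || w < 3) stop("degenerate crop: Sobel needs at least 3 x 3 pixels")
  ri <- 2:(h - 1); ci <- 2:(w - 1)
  gx <- (img[ri - 1, ci + 1] + 2 * img[ri, ci + 1] + img[ri + 1, ci + 1]) -
        (img[ri - 1, ci - 1] + 2 * img[ri, ci - 1] + img[ri + 1, ci - 1])
  gy <- (img[ri + 1, ci - 1] + 2 * img[ri + 1, ci] + img[ri + 1, ci + 1]) -
        (img[ri - 1, ci - 1] + 2 * img[ri - 1, ci] + img[ri - 1, ci + 1])
  list(gx = gx, gy = gy)
}

#' Tenengrad focus score on a crop around the optic disc
#'
#' Image-quality metric used to rank frames: the mean squared Sobel gradient
#' magnitude over a square crop of side `crop_factor` times the disc
#' bounding-box side, centred on the disc (clamped at frame borders).
#' Invariant to adding a constant intensity offset; strictly decreasing under
#' defocus blur.
#'
#' @param frame Numeric intensity matrix.
#' @param disc Disc geometry from [detect_disc()] (`list(center, radius)`).
#' @param crop_factor Crop side as a multiple of the disc diameter
#'   (default 1.5).
#' @return Non-negative scalar quality score.
#' @export
tenengrad_score <- function(frame, disc, crop_factor = 1.5) {
  frame <- as_frame_matrix(frame)
  stopifnot(!is.null(disc), disc$radius > 0)
  crop <- disc_crop(frame, disc, crop_factor)
  if (nrow(crop) < 3 || ncol(crop) < 3) {
    stop("degenerate crop: Sobel needs at least 3 x 3 pixels")
  }
  g <- sobel_gradients(crop)
  mean(g$gx^2 + g$gy^2)
}

#' Classify a frame as fundus / no-fundus
#'
#' Rule-based frame triage: a frame is a fundus view iff an optic disc is
#' detected and the fraction of vessel-like pixels (Frangi vesselness above
#' its hysteresis threshold) inside the disc crop exceeds `min_vessel_cover`.
#' Constant or pure-noise frames return `"no_fundus"`, never an error.
#'
#' @param frame Numeric intensity matrix.
#' @param min_vessel_cover Minimum vessel-pixel fraction inside the 1.5x disc
#'   crop.
#' @param crop_factor Crop factor passed to [disc_crop()].
#' @param vessel_thresh Vesselness threshold as a fraction of the crop's
#'   maximum response (matches the segmenter's high hysteresis threshold).
#' @param ... Passed to [detect_disc()].
#' @return `"fundus"` or `"no_fundus"`.
#' @export
classify_frame <- function(frame, min_vessel_cover = 0.02, crop_factor = 1.5,
                           vessel_thresh = 0.25, ...) {
  frame <- as_frame_matrix(frame)
  disc <- detect_disc(frame, ...)
  if (is.null(disc)) return("no_fundus")
  crop <- disc_crop(frame, disc, crop_factor)
  v <- frangi_vesselness(crop)
  # exclude the disc interior: its rim responds to the filter
  h <- nrow(crop); w <- ncol(crop)
  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  ys <- matrix(seq_len(h), h, w)
  ctr <- c((w + 1) / 2, (h + 1) / 2)
  inside <- sqrt((xs - ctr[1])^2 + (ys - ctr[2])^2) <= 1.15 * disc$radius
  vmax <- max(v)
  if (vmax <= 0) return("no_fundus")
  cover <- mean(v[!inside] >= vessel_thresh * vmax)
  if (!is.finite(cover) || cover < min_vessel_cover) return("no_fundus")
  "fundus"
}

#' Select the reference frame of a session
#'
#' The highest-quality fundus frame — argmax of the Tenengrad score over
#' frames classified as fundus, ties broken by the earliest timestamp. Errors
#' if the session contains no usable fundus frame (the session is then
#' excluded for image quality).
#'
#' @param stack A `frame_stack` (see [render_frames()] / [read_frames()]).
#' @param crop_factor Crop factor for [tenengrad_score()].
#' @param ... Passed to [classify_frame()].
#' @return `list(reference = index, triage = tibble)` where the triage tibble
#'   has one row per frame: frame_index, timestamp_s, frame_class, quality.
#' @export
select_reference <- function(stack, crop_factor = 1.5, ...) {
  n <- length(stack$frames)
  cls <- character(n)
  qual <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    f <- stack$frames[[i]]
    disc <- detect_disc(f)
    cls[i] <- classify_frame(f, crop_factor = crop_factor, ...)
    if (cls[i] == "fundus" && !is.null(disc)) {
      qual[i] <- tenengrad_score(f, disc, crop_factor)
    } else {
      cls[i] <- "no_fundus"
    }
  }
  triage <- tibble::tibble(
    frame_index = stack$info$frame_index,
    timestamp_s = stack$info$timestamp_s,
    frame_class = cls,
    quality = qual
  )
  cand <- which(cls == "fundus")
  if (length(cand) == 0) {
    stop("session excluded for image quality: no usable fundus frames")
  }
  best_q <- max(qual[cand])
  best <- cand[qual[cand] == best_q]
  ref <- best[which.min(stack$info$timestamp_s[best])]
  list(reference = ref, triage = triage)
}

#' Rigidly align a frame (or mask) to a reference by cross-correlation
#'
#' Translation-only registration: the integer shift maximising the circular
#' cross-correlation of the mean-subtracted images (computed via FFT) is
#' applied with constant fill. The normalised correlation of the overlapping
#' region at that shift gates acceptance: below `min_corr` the frame is
#' flagged unaligned and should be excluded.
#'
#' @param frame,reference Numeric matrices of identical dimensions.
#' @param min_corr Minimum Pearson correlation on the shifted overlap.
#' @param fill Fill value for exposed borders (default 0).
#' @return `list(aligned, dx, dy, correlation, ok)`: `aligned` is the shifted
#'   frame, `(dx, dy)` the applied shift in pixels, `ok` whether the
#'   correlation gate passed.
#' @export
align_to_reference <- function(frame, reference, min_corr = 0.3, fill = 0) {
  frame <- as_frame_matrix(frame); reference <- as_frame_matrix(reference)
  stopifnot(all(dim(frame) == dim(reference)))
  h <- nrow(frame); w <- ncol(frame)
  a <- frame - mean(frame)
  b <- reference - mean(reference)
  cc <- Re(stats::fft(stats::fft(b) * Conj(stats::fft(a)), inverse = TRUE))
  pk <- arrayInd(which.max(cc), dim(cc))
  dy <- pk[1] - 1; dx <- pk[2] - 1
  if (dy > h / 2) dy <- dy - h
  if (dx > w / 2) dx <- dx - w

  shifted <- shift_image(frame, dx, dy, fill = fill)
  ox <- max(1, 1 + dx):min(w, w + dx)
  oy <- max(1, 1 + dy):min(h, h + dy)
  r <- suppressWarnings(stats::cor(as.vector(shifted[oy, ox]),
                                   as.vector(reference[oy, ox])))
  if (!is.finite(r)) r <- 0
  list(aligned = shifted, dx = as.integer(dx), dy = as.integer(dy),
       correlation = r, ok = r >= min_corr)
}

#' Triage a full frame stack against its reference
#'
#' Runs [select_reference()] and then [align_to_reference()] for every fundus
#' frame, producing the per-frame report written by the pipeline: class,
#' quality, shift, and whether the frame is included (fundus, aligned).
#'
#' @param stack A `frame_stack`.
#' @param min_corr Alignment acceptance threshold.
#' @param ... Passed to [select_reference()].
#' @return `list(reference = index, report = tibble)` with report columns
#'   frame_index, timestamp_s, frame_class, quality, dx, dy, included, reason.
#' @export
triage_frames <- function(stack, min_corr = 0.3, ...) {
  sel <- select_reference(stack, ...)
  rep_tbl <- sel$triage
  n <- nrow(rep_tbl)
  dx <- rep(NA_integer_, n); dy <- rep(NA_integer_, n)
  included <- logical(n)
  reason <- character(n)
  ref_img <- stack$frames[[sel$reference]]
  for (i in seq_len(n)) {
    if (rep_tbl$frame_class[i] != "fundus") {
      reason[i] <- "no_fundus"
      next
    }
    al <- align_to_reference(stack$frames[[i]], ref_img, min_corr = min_corr)
    dx[i] <- al$dx; dy[i] <- al$dy
    if (!al$ok) {
      reason[i] <- "unaligned"
    } else {
      included[i] <- TRUE
      reason[i] <- "included"
    }
  }
  rep_tbl$dx <- dx; rep_tbl$dy <- dy
  rep_tbl$included <- included
  rep_tbl$reason <- reason
  list(reference = sel$reference, report = rep_tbl)
}
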