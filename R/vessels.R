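#' Crop a patch centred on a measurement point
#'
#' Cuts a `size x size` (default 128 x 128) patch centred on the point,
#' clamping the origin at frame borders so the patch always lies inside the
#' frame. Errors when the frame is smaller than the patch.
#'
#' @param frame Numeric matrix (intensity or mask).
#' @param point `c(x, y)` measurement-point coordinates (1-based).
#' @param size Patch side, pixels (default 128).
#' @return `list(patch, origin)` where `origin = c(x, y)` is the top-left
#'   pixel of the patch in frame coordinates, so
#'   `patch[r, c] == frame[origin[2] + r - 1, origin[1] + c - 1]`.
#' @export
crop_patch <- function(frame, point, size = 128) {
  frame <- as_frame_matrix(frame)
  h <- nrow(frame); w <- ncol(frame)
  if (h < size || w < size) {
    stop(sprintf("frame (%d x %d) smaller than the %d-pixel patch", w, h, size))
  }
  half <- floor(size / 2)
  ox <- clip(round(point[1]) - half, 1, w - size + 1)
  oy <- clip(round(point[2]) - half, 1, h - size + 1)
  list(
    patch = frame[oy:(oy + size - 1), ox:(ox + size - 1)],
    origin = c(x = ox, y = oy)
  )
}

# Width of one interpolated profile: full width at half depth. Works for dark
# vessels on bright background, bright bars (masks), or either (auto). The
# background level is the median of the outer quarters of the profile; the
# extremum is searched near the profile centre; the two half-depth crossings
# are located by linear interpolation. NA when the profile does not return to
# background on both sides.
width_from_profile <- function(vals, ts, polarity = "auto",
                               min_depth = 0.05) {
  ok <- is.finite(vals)
  if (mean(ok) < 0.9) return(NA_real_)  # profile exits the patch laterally
  n <- length(ts)
  k <- max(3, floor(n / 4))
  tails <- c(vals[seq_len(k)], vals[seq(n - k + 1, n)])
  bg <- stats::median(tails, na.rm = TRUE)
  if (!is.finite(bg)) return(NA_real_)

  central <- which(abs(ts) <= max(abs(ts)) / 2)
  if (polarity == "auto") {
    lo <- min(vals[central], na.rm = TRUE)
    hi <- max(vals[central], na.rm = TRUE)
    polarity <- if (bg - lo >= hi - bg) "dark" else "bright"
  }
  sgn <- if (polarity == "dark") -1 else 1
  prof <- sgn * (vals - bg)  # vessel is now a positive bump
  i_ext <- central[which.max(prof[central])]
  depth <- prof[i_ext]
  if (!is.finite(depth) || depth < min_depth) return(NA_real_)
  half <- depth / 2

  cross <- function(idx_seq) {
    prev <- i_ext
    for (i in idx_seq) {
      if (!is.finite(prof[i])) return(NA_real_)
      if (prof[i] <= half) {
        # linear interpolation between prev (above) and i (at/below)
        frac <- (prof[prev] - half) / (prof[prev] - prof[i])
        return(ts[prev] + frac * (ts[i] - ts[prev]))
      }
      prev <- i
    }
    NA_real_
  }
  t_r <- cross(seq(i_ext + 1, n))
  t_l <- cross(seq(i_ext - 1, 1))
  if (!is.finite(t_r) || !is.finite(t_l)) return(NA_real_)
  t_r - t_l
}

#' Perpendicular-profile widths along a centreline
#'
#' At each interior centreline pixel the local tangent is estimated over a
#' window of `tangent_window` path points each side; an intensity (or mask)
#' profile is sampled by bilinear interpolation along the perpendicular at
#' `step`-pixel spacing over `half_length` pixels each side, and its full
#' width at half depth is measured (half-minimum for dark vessels, mask-edge
#' half-crossing for masks). Lines whose profile never returns to background
#' (vessel exits the patch laterally) yield `NA` and are dropped from the
#' summary stage.
#'
#' @param patch Numeric matrix — an intensity patch or a (soft or 0/1) mask.
#' @param path `n x 2` (x, y) ordered centreline, e.g. from [centerline()].
#' @param step Sampling step along the perpendicular, pixels (default 0.1).
#' @param half_length Profile half-length, pixels (default 32).
#' @param tangent_window Path points each side used for the tangent
#'   (default 2).
#' @param polarity `"dark"`, `"bright"`, or `"auto"`.
#' @return Numeric vector of per-line widths (pixels, sub-pixel valued; may
#'   contain `NA` for dropped lines).
#' @export
perpendicular_widths <- function(patch, path, step = 0.1, half_length = 32,
                                 tangent_window = 2, polarity = "auto") {
  patch <- as_frame_matrix(patch)
  n <- nrow(path)
  if (n < 2 * tangent_window + 1 || n < 5) {
    stop("centreline too short to estimate local tangents")
  }
  # a short running mean irons out the staircase of the pixel skeleton so the
  # tangent (and hence the perpendicular) is not deflected by +/- one pixel
  # steps; profile centres stay on the raw path
  smooth1 <- function(z) {
    if (n < 7) return(z)
    f <- stats::filter(z, rep(1 / 5, 5), sides = 2)
    as.numeric(ifelse(is.na(f), z, f))
  }
  spath <- cbind(smooth1(path[, 1]), smooth1(path[, 2]))
  ts <- seq(-half_length, half_length, by = step)
  widths <- rep(NA_real_, n)
  for (i in seq(tangent_window + 1, n - tangent_window)) {
    a <- spath[i - tangent_window, ]; b <- spath[i + tangent_window, ]
    tx <- b[1] - a[1]; ty <- b[2] - a[2]
    nrm <- sqrt(tx^2 + ty^2)
    if (nrm == 0) next
    nx <- -ty / nrm; ny <- tx / nrm
    vals <- bilinear_sample(patch, path[i, 1] + ts * nx, path[i, 2] + ts * ny)
    widths[i] <- width_from_profile(vals, ts, polarity = polarity)
  }
  widths[seq(tangent_window + 1, n - tangent_window)]
}

#' Flag outlier widths and compute the robust mean width
#'
#' Outlier rule: modified z-score — a width is an outlier iff
#' `|w - median| > k * MAD` with the MAD scaled by 1.4826 for Gaussian
#' consistency. When the MAD degenerates to zero (a majority of identical
#' widths) the scaled mean absolute deviation (1.2533 x meanAD) takes its
#' place, the usual Iglewicz-Hoaglin fallback; when that is zero too (all
#' widths equal) no outliers are flagged. The mean is computed over the
#' retained lines only.
#'
#' @param line_widths Numeric widths (NAs are dropped first).
#' @param k Outlier threshold in scaled-MAD units (default 3).
#' @return `list(line_widths, outlier_mask, mean_width, n_lines, n_outliers)`.
#' @export
reject_outliers <- function(line_widths, k = 3) {
  w <- line_widths[is.finite(line_widths)]
  if (length(w) < 3) stop("insufficient measurement lines (need >= 3)")
  med <- stats::median(w)
  mad <- stats::mad(w)  # scaled by 1.4826
  if (mad == 0) mad <- 1.253314 * mean(abs(w - med))
  outlier <- if (mad == 0) rep(FALSE, length(w)) else abs(w - med) > k * mad
  list(
    line_widths = w,
    outlier_mask = outlier,
    mean_width = mean(w[!outlier]),
    n_lines = length(w),
    n_outliers = sum(outlier)
  )
}

#' Cross-sectional vessel area from its width
#'
#' Treats the vessel cross-section as circular: `area = pi * (width / 2)^2`.
#'
#' @param mean_width Vessel width (diameter), pixels; must be positive.
#' @return Area in pixels squared.
#' @export
vessel_area <- function(mean_width) {
  if (any(!is.finite(mean_width)) || any(mean_width <= 0)) {
    stop("vessel width must be positive")
  }
  pi * (mean_width / 2)^2
}

#' Arteriole/venule area ratio
#'
#' The A/V ratio used throughout the analysis is the ratio of cross-sectional
#' areas, `((artery_width/2)^2) / ((vein_width/2)^2) = (artery/vein)^2`; the
#' plain diameter ratio is available via `type = "diameter"`. A ratio above 1
#' (artery wider than vein) is unusual but valid — it is flagged, not
#' rejected.
#'
#' @param artery_width,vein_width Mean widths, pixels; both positive.
#' @param type `"area"` (default, squared diameter ratio) or `"diameter"`.
#' @return One-row tibble: artery_width, vein_width, av_area, flag_review.
#' @examples
#' av_ratio(8, 12)$av_area  # (8/12)^2 = 0.444...
#' @export
av_ratio <- function(artery_width, vein_width, type = c("area", "diameter")) {
  type <- match.arg(type)
  if (!is.finite(artery_width) || !is.finite(vein_width) ||
      artery_width <= 0 || vein_width <= 0) {
    stop("vessel widths must be positive")
  }
  r <- artery_width / vein_width
  val <- if (type == "area") r^2 else r
  tibble::tibble(
    artery_width = artery_width,
    vein_width = vein_width,
    av_area = val,
    flag_review = val > 1
  )
}

#' Place measurement points along the two largest vessels
#'
#' Rule-based stand-in for a learned point finder: the vessel mask is split
#' into connected components, the two largest retained, each skeletonised,
#' and `n_points` skeleton pixels selected per vessel at evenly spaced radial
#' distances from the disc centre (between `r_inner` and `r_outer` disc
#' radii). Vessels are labelled by calibre — the wider one (median distance-map
#' width along its skeleton) is the vein — unless ground truth supplies
#' labels.
#'
#' @param mask Logical vessel mask.
#' @param disc Disc geometry (`list(center, radius)`).
#' @param n_points Points per vessel.
#' @param r_inner,r_outer Radial band, in disc radii.
#' @param min_component Minimum component size, pixels.
#' @return Tibble: point_index, vessel_label ("artery"/"vein"), x, y,
#'   est_width. Warns when fewer than `n_points` are reachable or only one
#'   vessel is present (A/V undefined).
#' @export
place_measurement_points <- function(mask, disc, n_points = 3,
                                     r_inner = 1.3, r_outer = 4.5,
                                     min_component = 30) {
  stopifnot(!is.null(disc), n_points >= 0)
  if (n_points == 0) {
    return(tibble::tibble(point_index = integer(), vessel_label = character(),
                          x = numeric(), y = numeric(), est_width = numeric()))
  }
  if (!any(mask)) stop("empty vessel mask")
  lab <- EBImage::bwlabel(mask * 1)
  sizes <- tabulate(lab[lab > 0])
  big <- order(sizes, decreasing = TRUE)
  big <- big[sizes[big] >= min_component]
  if (length(big) == 0) stop("no vessel component large enough")
  if (length(big) == 1) {
    warning("only one vessel found: A/V ratio undefined for this frame")
  }
  big <- utils::head(big, 2)

  dm <- EBImage::distmap(mask * 1)
  res <- list()
  for (ci in seq_along(big)) {
    comp <- lab == big[ci]
    # skeletonise within the component bounding box only
    ys <- range(row(comp)[comp]); xs <- range(col(comp)[comp])
    sub <- comp[ys[1]:ys[2], xs[1]:xs[2], drop = FALSE]
    skel <- zhang_suen_thin(sub)
    sy <- row(skel)[skel] + ys[1] - 1
    sx <- col(skel)[skel] + xs[1] - 1
    if (length(sx) < 3) next
    rad <- sqrt((sx - disc$center[1])^2 + (sy - disc$center[2])^2)
    band <- rad >= r_inner * disc$radius & rad <= r_outer * disc$radius
    if (!any(band)) next
    sx <- sx[band]; sy <- sy[band]; rad <- rad[band]
    targets <- seq(min(rad), max(rad), length.out = n_points + 2)
    targets <- targets[2:(n_points + 1)]
    sel <- vapply(targets, function(r0) which.min(abs(rad - r0)), integer(1))
    sel <- unique(sel)
    res[[ci]] <- tibble::tibble(
      component = ci,
      point_index = seq_along(sel),
      x = sx[sel], y = sy[sel],
      est_width = 2 * stats::median(dm[cbind(sy, sx)])
    )
  }
  if (length(res) == 0) stop("no measurement points reachable")
  pts <- dplyr::bind_rows(res)
  n_found <- sum(!duplicated(pts$component)) # components with points
  widths <- vapply(split(pts$est_width, pts$component), mean, numeric(1))
  vein_comp <- as.integer(names(widths)[which.max(widths)])
  pts$vessel_label <- ifelse(
    pts$component == vein_comp & length(widths) > 1, "vein",
    ifelse(length(widths) > 1, "artery", NA_character_)
  )
  if (any(table(pts$component) < n_points)) {
    warning(sprintf("fewer than %d measurement points reachable on some vessel",
                    n_points))
  }
  dplyr::select(pts, "point_index", "vessel_label", "x", "y", "est_width")
}

#' Measure the vessel width at one measurement point
#'
#' Runs the patch pipeline at a single point: crop a `patch_size` patch
#' (from the intensity frame or a mask), extract the centreline from the mask
#' patch, sample perpendicular profiles, reject outlier widths, and summarise.
#'
#' @param frame Intensity frame (used for profile sampling when
#'   `measure_on = "intensity"`).
#' @param mask Vessel mask (used for the centreline, and for profiles when
#'   `measure_on = "mask"`).
#' @param point `c(x, y)` measurement point.
#' @param patch_size Patch side, pixels.
#' @param measure_on `"intensity"` or `"mask"`.
#' @param outlier_k Outlier threshold, scaled-MAD units.
#' @param ... Passed to [perpendicular_widths()].
#' @return One-row tibble: x, y, mean_width, n_lines, n_outliers; or NULL when
#'   no centreline is found at the point.
#' @export
measure_point <- function(frame, mask, point, patch_size = 128,
                          measure_on = c("intensity", "mask"),
                          outlier_k = 3, ...) {
  measure_on <- match.arg(measure_on)
  mp <- crop_patch(mask * 1, point, patch_size)
  path <- centerline(mp$patch)
  if (is.null(path)) return(NULL)
  target <- if (measure_on == "intensity") {
    crop_patch(frame, point, patch_size)$patch
  } else {
    mp$patch
  }
  lw <- perpendicular_widths(target, path, ...)
  if (sum(is.finite(lw)) < 3) return(NULL)
  s <- reject_outliers(lw, k = outlier_k)
  tibble::tibble(
    x = point[1], y = point[2],
    mean_width = s$mean_width,
    n_lines = s$n_lines,
    n_outliers = s$n_outliers
  )
}

#' Measure the A/V area ratio on one frame
#'
#' Full Fig.-1-style measurement for a single fundus frame: vessel
#' segmentation (unless a mask is supplied), measurement-point placement,
#' per-point perpendicular-width measurement for both vessels, and the
#' per-point-pair A/V area ratio (artery point k paired with vein point k).
#'
#' @param frame Intensity frame.
#' @param disc Disc geometry; detected automatically when NULL.
#' @param mask Optional precomputed vessel mask.
#' @param n_points Measurement points per vessel.
#' @param truth_labels Optional named list mapping `artery`/`vein` to
#'   ground-truth centrelines (n x 2 x,y); when given, component labels are
#'   assigned by proximity to the true centrelines instead of by calibre.
#' @param ... Passed to [measure_point()].
#' @return `list(points, pairs)`: `points` is the per-point width table
#'   (vessel_label, x, y, mean_width, n_lines, n_outliers), `pairs` the
#'   per-pair tibble (point_index, artery_width, vein_width, av_area).
#' @export
measure_frame <- function(frame, disc = NULL, mask = NULL, n_points = 3,
                          truth_labels = NULL, ...) {
  frame <- as_frame_matrix(frame)
  if (is.null(disc)) disc <- detect_disc(frame)
  if (is.null(disc)) stop("no optic disc found: frame not measurable")
  if (is.null(mask)) mask <- segment_vessels(frame, disc)
  pts <- place_measurement_points(mask, disc, n_points = n_points)
  if (!is.null(truth_labels)) {
    pts$vessel_label <- vapply(seq_len(nrow(pts)), function(i) {
      d <- vapply(truth_labels, function(cl) {
        min(sqrt((cl[, 1] - pts$x[i])^2 + (cl[, 2] - pts$y[i])^2))
      }, numeric(1))
      names(truth_labels)[which.min(d)]
    }, character(1))
  }
  meas <- list()
  for (i in seq_len(nrow(pts))) {
    m <- measure_point(frame, mask, c(pts$x[i], pts$y[i]), ...)
    if (is.null(m)) next
    m$vessel_label <- pts$vessel_label[i]
    m$point_index <- pts$point_index[i]
    meas[[length(meas) + 1]] <- m
  }
  if (length(meas) == 0) stop("no measurable points on this frame")
  points <- dplyr::bind_rows(meas)

  art <- dplyr::filter(points, .data$vessel_label == "artery")
  ven <- dplyr::filter(points, .data$vessel_label == "vein")
  pairs <- NULL
  if (nrow(art) > 0 && nrow(ven) > 0) {
    npair <- min(nrow(art), nrow(ven))
    pairs <- purrr::map_dfr(seq_len(npair), function(k) {
      r <- av_ratio(art$mean_width[k], ven$mean_width[k])
      r$point_index <- k
      r
    })
  }
  list(points = points, pairs = pairs)
}
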