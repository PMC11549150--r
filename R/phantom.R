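#' Specification of a fundus phantom frame sequence
#'
#' Describes a synthetic monochrome fundus video: a bright optic disc and one
#' arteriole/venule pair of constant, known diameter drawn as smooth quadratic
#' curves leaving the disc, with small rigid inter-frame motion, optional
#' defocus blur and sensor noise, and an interleaved fraction of non-fundus
#' (pure noise) frames. The geometry is deliberately simple — the phantom
#' exists to exercise the width-measurement pipeline against ground truth, not
#' to look like a retina.
#'
#' @param image_size `c(width, height)` in pixels; default 1280 x 1024, the
#'   native frame size of the handheld monochrome fundus camera emulated here.
#' @param disc_center `c(x, y)` optic-disc centre in pixels (1-based, x =
#'   column, y = row, origin top-left). Default scales with the image.
#' @param disc_radius Disc radius, pixels. The disc must lie fully inside the
#'   frame.
#' @param artery_width,vein_width True vessel diameters, pixels (> 1).
#' @param vessel_contrast Vessel depth as a fraction of full scale, in [0, 1].
#' @param blur_sigma Gaussian defocus blur SD, pixels (0 = none).
#' @param noise_sigma Additive Gaussian noise SD, intensity units (frames are
#'   in [0, 1]).
#' @param n_frames Number of frames.
#' @param frame_rate Frames per second (default 15).
#' @param motion_amplitude Maximum rigid per-frame shift, pixels (integer
#'   shifts are drawn uniformly in `[-motion_amplitude, motion_amplitude]`).
#' @param fraction_nonfundus Probability that a frame is pure noise, in [0, 1).
#' @param seed Integer seed; rendering is bit-reproducible.
#' @return A list of class `frame_phantom_spec`.
#' @seealso [render_frames()]
#' @export
frame_phantom_spec <- function(image_size = c(1280, 1024),
                               disc_center = NULL,
                               disc_radius = 80,
                               artery_width = 8,
                               vein_width = 12,
                               vessel_contrast = 0.35,
                               blur_sigma = 0.8,
                               noise_sigma = 0.02,
                               n_frames = 10,
                               frame_rate = 15,
                               motion_amplitude = 3,
                               fraction_nonfundus = 0,
                               seed = 1L) {
  if (is.null(disc_center)) {
    disc_center <- round(c(0.40, 0.45) * image_size)
  }
  if (artery_width < 1 || vein_width < 1) {
    stop("vessel width below 1 pixel: phantom is unmeasurable")
  }
  stopifnot(
    length(image_size) == 2, all(image_size >= 32),
    vessel_contrast >= 0, vessel_contrast <= 1,
    blur_sigma >= 0, noise_sigma >= 0, n_frames >= 1, frame_rate > 0,
    motion_amplitude >= 0,
    fraction_nonfundus >= 0, fraction_nonfundus < 1
  )
  margin <- disc_radius + motion_amplitude + 2
  if (disc_center[1] - margin < 1 || disc_center[1] + margin > image_size[1] ||
      disc_center[2] - margin < 1 || disc_center[2] + margin > image_size[2]) {
    stop("optic disc (plus motion margin) must lie fully inside the image")
  }
  structure(
    list(
      image_size = as.integer(image_size),
      disc_center = disc_center,
      disc_radius = disc_radius,
      artery_width = artery_width,
      vein_width = vein_width,
      vessel_contrast = vessel_contrast,
      blur_sigma = blur_sigma,
      noise_sigma = noise_sigma,
      n_frames = as.integer(n_frames),
      frame_rate = frame_rate,
      motion_amplitude = motion_amplitude,
      fraction_nonfundus = fraction_nonfundus,
      seed = as.integer(seed)
    ),
    class = "frame_phantom_spec"
  )
}

# Quadratic Bezier sampled densely enough that the polyline approximates the
# curve to well under the stamping tolerance.
bezier_points <- function(p0, p1, p2, step = 0.3) {
  chord <- sum(sqrt(diff(c(p0[1], p1[1], p2[1]))^2 +
                    diff(c(p0[2], p1[2], p2[2]))^2))
  n <- max(16, ceiling(chord / step))
  t <- seq(0, 1, length.out = n)
  cbind(
    x = (1 - t)^2 * p0[1] + 2 * t * (1 - t) * p1[1] + t^2 * p2[1],
    y = (1 - t)^2 * p0[2] + 2 * t * (1 - t) * p1[2] + t^2 * p2[2]
  )
}

# Distance from every pixel to a polyline, computed by stamping a window
# around each sample point; pixels farther than `reach` stay Inf.
polyline_distance <- function(pts, width, height, reach) {
  d <- matrix(Inf, nrow = height, ncol = width)
  r <- ceiling(reach)
  offs <- seq(-r, r)
  for (i in seq_len(nrow(pts))) {
    cx <- pts[i, 1]; cy <- pts[i, 2]
    xs <- round(cx) + offs
    ys <- round(cy) + offs
    keep_x <- xs >= 1 & xs <= width
    keep_y <- ys >= 1 & ys <= height
    if (!any(keep_x) || !any(keep_y)) next
    xs <- xs[keep_x]; ys <- ys[keep_y]
    dd <- sqrt(outer((ys - cy)^2, (xs - cx)^2, `+`))
    blk <- d[ys, xs, drop = FALSE]
    d[ys, xs] <- pmin(blk, dd)
  }
  d
}

# Vessel paths for a phantom: two quadratic curves leaving the disc rim at
# +/- 28 degrees from the +x axis, curving gently apart. `rot` rotates the
# whole pair about the disc centre (used for rotation-invariance checks).
phantom_vessel_paths <- function(spec, rot = 0) {
  cc <- spec$disc_center
  R <- spec$disc_radius
  u <- function(a) c(cos(a), sin(a))
  mk <- function(theta, bend) {
    p0 <- cc + (R - 2) * u(theta)
    p1 <- cc + 2.6 * R * u(theta + bend)
    p2 <- cc + 5.0 * R * u(theta - bend / 2)
    bezier_points(p0, p1, p2)
  }
  list(
    artery = mk(rot - 28 * pi / 180, 10 * pi / 180),
    vein   = mk(rot + 28 * pi / 180, -10 * pi / 180)
  )
}

# Render the noise-free, unshifted base frame. Edge profiles are linear ramps
# whose half-depth point sits exactly at distance width/2 from the centreline,
# so the drawn full width at half depth equals the nominal width.
render_base_frame <- function(spec, rot = 0, edge = 0.75, bg = 0.45,
                              disc_amp = 0.30) {
  w <- spec$image_size[1]; h <- spec$image_size[2]
  xs <- matrix(seq_len(w), nrow = h, ncol = w, byrow = TRUE)
  ys <- matrix(seq_len(h), nrow = h, ncol = w)
  dd <- sqrt((xs - spec$disc_center[1])^2 + (ys - spec$disc_center[2])^2)
  img <- bg + disc_amp * clip((spec$disc_radius + 1.5 - dd) / 3, 0, 1)

  paths <- phantom_vessel_paths(spec, rot = rot)
  widths <- c(artery = spec$artery_width, vein = spec$vein_width)
  for (v in names(paths)) {
    half <- widths[[v]] / 2
    dist <- polyline_distance(paths[[v]], w, h, reach = half + edge + 1)
    img <- img - spec$vessel_contrast * clip((half + edge - dist) / (2 * edge), 0, 1)
  }
  if (spec$blur_sigma > 0) {
    img <- EBImage::gblur(img, sigma = spec$blur_sigma)
  }
  list(image = clip(img, 0, 1), paths = paths, bg = bg)
}

shift_image <- function(img, dx, dy, fill) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(fill, h, w)
  src_x <- seq_len(w) - dx
  src_y <- seq_len(h) - dy
  ok_x <- src_x >= 1 & src_x <= w
  ok_y <- src_y >= 1 & src_y <= h
  out[ok_y, ok_x] <- img[src_y[ok_y], src_x[ok_x]]
  out
}

#' Render a phantom fundus frame sequence with ground truth
#'
#' Produces the frame stack described by a [frame_phantom_spec()]: fundus
#' frames contain a bright disc and two dark constant-width vessels, shifted
#' per frame by a random integer rigid translation of at most
#' `motion_amplitude` pixels; a `fraction_nonfundus` of frames are pure noise.
#' Ground truth (true widths, disc geometry, per-frame shifts and fundus
#' flags, dense vessel centrelines) is returned alongside, so downstream
#' measurements can be scored.
#'
#' @param spec A [frame_phantom_spec()].
#' @param rotation Rotate the vessel pair about the disc centre by this many
#'   radians (geometry-level rotation; used for rotation-invariance tests).
#' @return An object of class `frame_stack`: a list with
#'   \describe{
#'     \item{frames}{list of `height x width` numeric matrices in [0, 1]}
#'     \item{info}{tibble: frame_index, timestamp_s, is_fundus, dx, dy}
#'     \item{truth}{list: disc_center, disc_radius, artery_width, vein_width,
#'       av_area (= (artery/vein)^2), centerlines (list of x,y matrices),
#'       background}
#'   }
#' @examples
#' st <- render_frames(frame_phantom_spec(image_size = c(320, 256),
#'                                        disc_center = c(110, 120),
#'                                        disc_radius = 30, n_frames = 2))
#' st$info
#' @export
render_frames <- function(spec = frame_phantom_spec(), rotation = 0) {
  stopifnot(inherits(spec, "frame_phantom_spec"))
  set.seed(spec$seed)
  base <- render_base_frame(spec, rot = rotation)

  n <- spec$n_frames
  is_fundus <- stats::runif(n) >= spec$fraction_nonfundus
  amp <- spec$motion_amplitude
  draw_shift <- function() {
    if (amp < 1) return(integer(n))
    sample(seq(-floor(amp), floor(amp)), n, replace = TRUE)
  }
  dx <- ifelse(is_fundus, draw_shift(), 0L)
  dy <- ifelse(is_fundus, draw_shift(), 0L)
  # first fundus frame is the unshifted canonical view
  first_f <- which(is_fundus)[1]
  if (!is.na(first_f)) dx[first_f] <- dy[first_f] <- 0L

  h <- spec$image_size[2]; w <- spec$image_size[1]
  frames <- vector("list", n)
  for (i in seq_len(n)) {
    if (is_fundus[i]) {
      f <- shift_image(base$image, dx[i], dy[i], fill = base$bg)
    } else {
      f <- matrix(base$bg, h, w)
    }
    if (spec$noise_sigma > 0) {
      f <- f + matrix(stats::rnorm(h * w, 0, spec$noise_sigma), h, w)
    }
    frames[[i]] <- clip(f, 0, 1)
  }

  structure(
    list(
      frames = frames,
      info = tibble::tibble(
        frame_index = seq_len(n),
        timestamp_s = (seq_len(n) - 1) / spec$frame_rate,
        is_fundus = is_fundus,
        dx = as.integer(dx),
        dy = as.integer(dy)
      ),
      truth = list(
        disc_center = spec$disc_center,
        disc_radius = spec$disc_radius,
        artery_width = spec$artery_width,
        vein_width = spec$vein_width,
        av_area = (spec$artery_width / spec$vein_width)^2,
        centerlines = base$paths,
        background = base$bg
      ),
      spec = spec
    ),
    class = "frame_stack"
  )
}

#' Ground-truth vessel mask of a phantom
#'
#' Binary mask of pixels within half the nominal width of either drawn
#' centreline, excluding the disc interior — the reference against which
#' [segment_vessels()] output is scored.
#'
#' @param stack A [render_frames()] result.
#' @param disc_exclusion Multiple of the disc radius to carve out (default
#'   1.3, matching the segmenter's own exclusion zone).
#' @return Logical `height x width` matrix.
#' @export
phantom_truth_mask <- function(stack, disc_exclusion = 1.3) {
  spec <- stack$spec
  w <- spec$image_size[1]; h <- spec$image_size[2]
  tr <- stack$truth
  mask <- matrix(FALSE, h, w)
  for (v in c("artery", "vein")) {
    half <- if (v == "artery") tr$artery_width / 2 else tr$vein_width / 2
    d <- polyline_distance(tr$centerlines[[v]], w, h, reach = half + 1)
    mask <- mask | (d <= half)
  }
  xs <- matrix(seq_len(w), nrow = h, ncol = w, byrow = TRUE)
  ys <- matrix(seq_len(h), nrow = h, ncol = w)
  dd <- sqrt((xs - tr$disc_center[1])^2 + (ys - tr$disc_center[2])^2)
  mask & (dd > disc_exclusion * tr$disc_radius)
}

#' Write / read a frame stack as PNG files plus frames.csv
#'
#' Frames are written as 8-bit grayscale PNGs named `frame_%06d.png` together
#' with `frames.csv` (`frame_index`, `timestamp_s`) and, for phantoms, a
#' `ground_truth.json` sidecar.
#'
#' @param stack A `frame_stack`.
#' @param dir Output directory (created if needed).
#' @param truth Write the ground-truth sidecar? Default TRUE.
#' @return `write_frames()`: `dir`, invisibly. `read_frames()`: a
#'   `frame_stack` (with `truth = NULL` unless a sidecar is present).
#' @export
write_frames <- function(stack, dir, truth = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(stack$frames)) {
    png::writePNG(stack$frames[[i]],
                  file.path(dir, sprintf("frame_%06d.png", i)))
  }
  readr::write_csv(stack$info[, c("frame_index", "timestamp_s")],
                   file.path(dir, "frames.csv"))
  if (truth && !is.null(stack$truth)) {
    tr <- stack$truth
    side <- list(
      disc_center = tr$disc_center, disc_radius = tr$disc_radius,
      artery_width = tr$artery_width, vein_width = tr$vein_width,
      av_area = tr$av_area, background = tr$background,
      is_fundus = stack$info$is_fundus,
      dx = stack$info$dx, dy = stack$info$dy,
      centerlines = lapply(tr$centerlines, function(m) {
        list(x = unname(m[, 1]), y = unname(m[, 2]))
      })
    )
    jsonlite::write_json(side, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_frames
#' @export
read_frames <- function(dir) {
  info <- readr::read_csv(file.path(dir, "frames.csv"),
                          show_col_types = FALSE)
  frames <- lapply(info$frame_index, function(i) {
    m <- png::readPNG(file.path(dir, sprintf("frame_%06d.png", i)))
    if (length(dim(m)) == 3) m <- m[, , 1]
    m
  })
  truth <- NULL
  tpath <- file.path(dir, "ground_truth.json")
  if (file.exists(tpath)) {
    side <- jsonlite::read_json(tpath, simplifyVector = TRUE)
    truth <- list(
      disc_center = side$disc_center, disc_radius = side$disc_radius,
      artery_width = side$artery_width, vein_width = side$vein_width,
      av_area = side$av_area, background = side$background,
      centerlines = lapply(side$centerlines, function(p) {
        cbind(x = p$x, y = p$y)
      })
    )
    info$is_fundus <- side$is_fundus
    info$dx <- side$dx
    info$dy <- side$dy
  }
  structure(list(frames = frames, info = info, truth = truth, spec = NULL),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("<frame_stack: %d frames, %d x %d px, %d fundus>\n",
              length(x$frames), ncol(x$frames[[1]]), nrow(x$frames[[1]]),
              sum(x$info$is_fundus %||% NA)))
  invisible(x)
}
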