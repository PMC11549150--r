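# Frangi-style 2-D vesselness for dark tubular structures.
#
# Hessian entries are computed by central differences on a Gaussian-smoothed
# image and scale-normalised (multiplied by sigma^2). For dark vessels on a
# brighter background the large-magnitude eigenvalue is positive across the
# vessel; responses with lambda2 < 0 are zeroed.

hessian_at_scale <- function(img, sigma) {
  sm <- EBImage::gblur(img, sigma = sigma)
  h <- nrow(sm); w <- ncol(sm)
  z <- matrix(0, h, w)
  dxx <- z; dyy <- z; dxy <- z
  ci <- 2:(w - 1); ri <- 2:(h - 1)
  dxx[, ci] <- sm[, ci + 1] - 2 * sm[, ci] + sm[, ci - 1]
  dyy[ri, ] <- sm[ri + 1, ] - 2 * sm[ri, ] + sm[ri - 1, ]
  dxy[ri, ci] <- (sm[ri + 1, ci + 1] + sm[ri - 1, ci - 1] -
                  sm[ri + 1, ci - 1] - sm[ri - 1, ci + 1]) / 4
  s2 <- sigma^2
  list(dxx = dxx * s2, dyy = dyy * s2, dxy = dxy * s2)
}

#' Frangi vesselness of a monochrome image
#'
#' Multiscale tubular-structure enhancement for dark vessels: at each scale
#' the Hessian eigenvalues \eqn{|\lambda_1| \le |\lambda_2|} feed the Frangi
#' blobness ratio \eqn{R_b = \lambda_1/\lambda_2} and structureness
#' \eqn{S = \sqrt{\lambda_1^2 + \lambda_2^2}}; the response
#' \eqn{\exp(-R_b^2/2\beta^2)\,(1 - \exp(-S^2/2c^2))} is kept where
#' \eqn{\lambda_2 > 0} (intensity minimum across the tube) and maximised over
#' scales.
#'
#' @param img Numeric intensity matrix in [0, 1].
#' @param scales Gaussian scales (SD, pixels); match to half the expected
#'   vessel radii.
#' @param beta Blobness sensitivity (default 0.5, the conventional value).
#' @param c_frac Structureness constant as a fraction of the maximum
#'   structureness at each scale (default 0.5, the conventional "half max
#'   Hessian norm" rule).
#' @return Matrix of vesselness values in [0, 1].
#' @export
frangi_vesselness <- function(img, scales = c(1.5, 2.5, 4), beta = 0.5,
                              c_frac = 0.5) {
  img <- as_frame_matrix(img)
  out <- matrix(0, nrow(img), ncol(img))
  for (s in scales) {
    hs <- hessian_at_scale(img, s)
    tr <- hs$dxx + hs$dyy
    disc <- sqrt(pmax((hs$dxx - hs$dyy)^2 + 4 * hs$dxy^2, 0))
    e1 <- (tr - disc) / 2
    e2 <- (tr + disc) / 2
    # order by |eigenvalue|: lambda2 is the larger magnitude
    swap <- abs(e1) > abs(e2)
    l1 <- ifelse(swap, e2, e1)
    l2 <- ifelse(swap, e1, e2)
    S2 <- l1^2 + l2^2
    c2 <- (c_frac * sqrt(max(S2)))^2
    if (c2 == 0) next
    rb2 <- ifelse(l2 != 0, (l1 / l2)^2, 0)
    v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-S2 / (2 * c2)))
    v[l2 <= 0] <- 0
    out <- pmax(out, v)
  }
  out
}

#' Segment retinal vessels with vesselness + hysteresis thresholding
#'
#' Classical stand-in for a learned vessel segmenter: Frangi vesselness is
#' thresholded hysteretically (connected components of the low mask are kept
#' when they contain at least one high-mask pixel), gated to pixels darker
#' than the frame median, and the optic-disc interior excluded; an optional
#' closing+dilation can grow the mask. Binary masks may instead be
#' supplied directly to the measurement functions, so the geometric core is
#' testable independently of segmentation quality.
#'
#' @param frame Numeric intensity matrix.
#' @param disc Optional disc geometry (`list(center, radius)`); its interior
#'   (up to `disc_exclusion` times the radius) is removed from the mask.
#' @param scales Vesselness scales, pixels.
#' @param hi,lo Hysteresis thresholds as fractions of the maximum vesselness.
#' @param disc_exclusion Disc exclusion zone multiplier.
#' @param min_size Minimum connected-component size, pixels.
#' @param grow Radius of an optional final closing+dilation, pixels (default 0:
#'   the hysteresis mask already spans the full vessel width, and growing can
#'   bridge adjacent vessels near the disc).
#' @param dark_offset Vessels must be at least this much darker than the
#'   median frame intensity; suppresses the filter's ring response on the
#'   dark side of the bright disc rim (NA disables the gate).
#' @return Logical matrix. Errors if the mask comes out empty (session-level
#'   exclusion signal).
#' @export
segment_vessels <- function(frame, disc = NULL, scales = c(1.5, 2.5, 4),
                            hi = 0.25, lo = 0.08, disc_exclusion = 1.3,
                            min_size = 30, grow = 0, dark_offset = 0.02) {
  frame <- as_frame_matrix(frame)
  v <- frangi_vesselness(frame, scales = scales)
  vmax <- max(v)
  if (vmax <= 0) stop("empty vessel mask: no tubular structure found")
  low <- v >= lo * vmax
  high <- v >= hi * vmax
  lab <- EBImage::bwlabel(low)
  keep_ids <- setdiff(unique(lab[high]), 0)
  mask <- matrix(lab %in% keep_ids, nrow(frame), ncol(frame))
  dark <- NULL
  if (is.finite(dark_offset)) {
    dark <- frame <= stats::median(frame) - dark_offset
    mask <- mask & dark
  }

  if (!is.null(disc)) {
    xs <- matrix(seq_len(ncol(frame)), nrow(frame), ncol(frame), byrow = TRUE)
    ys <- matrix(seq_len(nrow(frame)), nrow(frame), ncol(frame))
    dd <- sqrt((xs - disc$center[1])^2 + (ys - disc$center[2])^2)
    mask[dd <= disc_exclusion * disc$radius] <- FALSE
  }
  if (grow > 0) {
    k <- EBImage::makeBrush(2 * grow + 1, shape = "disc")
    mask <- EBImage::closing(mask * 1, k) > 0
    mask <- EBImage::dilate(mask * 1, k) > 0
    # dilation may not cross back over the darkness gate's complement by more
    # than the grow radius, but re-check the disc zone it can re-enter
    if (!is.null(disc)) {
      xs <- matrix(seq_len(ncol(frame)), nrow(frame), ncol(frame), byrow = TRUE)
      ys <- matrix(seq_len(nrow(frame)), nrow(frame), ncol(frame))
      dd <- sqrt((xs - disc$center[1])^2 + (ys - disc$center[2])^2)
      mask[dd <= disc_exclusion * disc$radius] <- FALSE
    }
  }
  lab2 <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab2[lab2 > 0])
  small <- which(sizes < min_size)
  if (length(small)) mask[lab2 %in% small] <- FALSE
  if (!any(mask)) stop("empty vessel mask: no tubular structure found")
  mask
}
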