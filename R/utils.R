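`%||%` <- function(x, y) if (is.null(x)) y else x

# Bilinear interpolation of img (h x w matrix, 1-based x = col, y = row) at
# arbitrary coordinates; NA outside the grid.
bilinear_sample <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  out <- rep(NA_real_, length(x))
  ok <- x >= 1 & x <= w & y >= 1 & y <= h
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]
  x0 <- pmin(floor(x), w - 1); y0 <- pmin(floor(y), h - 1)
  fx <- x - x0; fy <- y - y0
  v00 <- img[cbind(y0, x0)]
  v01 <- img[cbind(y0, x0 + 1)]
  v10 <- img[cbind(y0 + 1, x0)]
  v11 <- img[cbind(y0 + 1, x0 + 1)]
  out[ok] <- v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
    v10 * (1 - fx) * fy + v11 * fx * fy
  out
}

as_frame_matrix <- function(frame) {
  if (inherits(frame, "Image")) frame <- EBImage::imageData(frame)
  stopifnot(is.matrix(frame), is.numeric(frame))
  frame
}
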