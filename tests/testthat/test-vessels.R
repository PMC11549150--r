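test_that("crop_patch centres, clamps and indexes exactly", {
  f <- matrix(seq_len(1280 * 1024) / (1280 * 1024), 1024, 1280)
  cp <- crop_patch(f, c(640, 512))
  expect_equal(unname(cp$origin), c(640 - 64, 512 - 64))
  expect_equal(dim(cp$patch), c(128, 128))
  cp2 <- crop_patch(f, c(10, 10))
  expect_equal(unname(cp2$origin), c(1, 1))
  # round-trip indexing identity
  expect_equal(cp$patch[5, 9], f[cp$origin[2] + 4, cp$origin[1] + 8])
  expect_error(crop_patch(matrix(0, 100, 100), c(50, 50)), "smaller")
})

test_that("centerline recovers the axis of horizontal, diagonal and spurred bars", {
  # horizontal bar of height 9 centred on row 64 -> middle row
  m <- matrix(FALSE, 128, 128)
  m[60:68, ] <- TRUE
  path <- centerline(m)
  expect_false(is.null(path))
  expect_true(all(path[, 2] == 64))

  # 45-degree bar -> centreline on the diagonal within 1 px
  xs <- matrix(seq_len(128), 128, 128, byrow = TRUE)
  ys <- matrix(seq_len(128), 128, 128)
  diag_m <- abs(xs - ys) / sqrt(2) <= 4
  dpath <- centerline(diag_m)
  expect_false(is.null(dpath))
  expect_lt(max(abs(dpath[, 1] - dpath[, 2]) / sqrt(2)), 1 + 1e-9)

  # a short side-spur must not change the extracted path length
  spur <- m
  spur[48:59, 64] <- TRUE
  spath <- centerline(spur)
  expect_equal(nrow(spath), nrow(path))

  expect_null(centerline(matrix(FALSE, 64, 64)))
})

test_that("perpendicular widths match the analytic bar width across orientations", {
  for (ang_deg in seq(0, 165, by = 15)) {
    patch <- soft_bar_patch(width = 12, angle = ang_deg * pi / 180)
    path <- centerline(patch)
    expect_false(is.null(path))
    w <- perpendicular_widths(patch, path, polarity = "bright")
    expect_lt(abs(median(w, na.rm = TRUE) - 12), 0.25)
  }
})

test_that("an ideal bar mask yields near-constant line widths", {
  patch <- soft_bar_patch(width = 12, angle = 0.3)
  path <- centerline(patch)
  w <- perpendicular_widths(patch, path)
  w <- w[is.finite(w)]
  expect_gt(length(w), 50)
  expect_true(all(abs(w - 12) <= 0.2))
})

test_that("a symmetric triangular dip has the analytic half-depth width", {
  # triangular profile of base 10 (half-width 5) -> FWHM = 5, exactly
  ts <- seq(-32, 32, by = 0.1)
  vals <- 1 - 0.5 * pmax(0, 1 - abs(ts) / 5)
  expect_equal(retinaicp:::width_from_profile(vals, ts, polarity = "dark"), 5,
               tolerance = 1e-9)
  # a line leaving the patch laterally (out-of-patch samples are NA) is dropped
  vals2 <- vals
  vals2[ts < -20] <- NA
  expect_true(is.na(retinaicp:::width_from_profile(vals2, ts, polarity = "dark")))
})

test_that("outlier rejection implements the modified z-score with MAD fallback", {
  r <- reject_outliers(c(10, 10, 10, 10))
  expect_equal(r$n_outliers, 0)
  expect_equal(r$mean_width, 10)

  r2 <- reject_outliers(c(10, 10, 10, 10, 30))
  expect_equal(r2$n_outliers, 1)
  expect_true(r2$outlier_mask[5])
  expect_equal(r2$mean_width, 10)

  r3 <- reject_outliers(c(7, 7, 7))
  expect_equal(r3$n_outliers, 0)
  expect_equal(r3$mean_width, 7)

  # brute-force modified z-score on a non-degenerate sample
  w <- c(9.8, 10.1, 10.0, 9.9, 10.2, 14.5)
  med <- median(w); s <- 1.4826 * median(abs(w - med))
  expect_equal(reject_outliers(w)$outlier_mask, abs(w - med) / s > 3)

  expect_error(reject_outliers(c(5, 6)), "insufficient")
})

test_that("area and ratio formulas follow the circular cross-section model", {
  expect_equal(vessel_area(2), pi)
  expect_equal(vessel_area(10), 25 * pi)
  expect_error(vessel_area(0), "positive")

  expect_equal(av_ratio(8, 12)$av_area, (8 / 12)^2)
  expect_equal(av_ratio(7, 7)$av_area, 1)
  r <- av_ratio(12, 8)
  expect_equal(r$av_area, 2.25)
  expect_true(r$flag_review)
  expect_error(av_ratio(-1, 5), "positive")
  expect_equal(av_ratio(8, 12, type = "diameter")$av_area, 2 / 3)
  # reciprocal identity (exact up to one floating-point rounding)
  for (pair in list(c(5, 9), c(11.2, 7.3), c(4, 4))) {
    expect_equal(av_ratio(pair[1], pair[2])$av_area *
                   av_ratio(pair[2], pair[1])$av_area, 1, tolerance = 1e-14)
  }
})

test_that("vesselness segmentation recovers the phantom mask", {
  st <- small_stack()
  f <- st$frames[[1]]
  mask <- segment_vessels(f, detect_disc(f))
  gt <- phantom_truth_mask(st)
  recall <- sum(mask & gt) / sum(gt)
  fp_rate <- sum(mask & !gt) / sum(!gt)
  dice <- 2 * sum(mask & gt) / (sum(mask) + sum(gt))
  expect_gte(recall, 0.95)
  expect_lte(fp_rate, 0.02)
  expect_gte(dice, 0.7)
  expect_error(segment_vessels(matrix(0.5, 200, 200)), "empty vessel mask")
})

test_that("measurement points land on the vessels and respect n_points", {
  st <- small_stack()
  f <- st$frames[[1]]
  disc <- detect_disc(f)
  mask <- segment_vessels(f, disc)
  pts <- place_measurement_points(mask, disc, n_points = 3)
  expect_equal(nrow(pts), 6)
  expect_setequal(unique(pts$vessel_label), c("artery", "vein"))
  # each point lies within 2 px of a true centreline, and labels agree
  for (i in seq_len(nrow(pts))) {
    d <- vapply(st$truth$centerlines, function(cl) {
      min(sqrt((cl[, 1] - pts$x[i])^2 + (cl[, 2] - pts$y[i])^2))
    }, numeric(1))
    expect_lt(min(d), 2.5)
    expect_equal(names(which.min(d)), pts$vessel_label[i])
  }
  expect_equal(nrow(place_measurement_points(mask, disc, n_points = 0)), 0)
  # single-vessel mask: A/V undefined
  one <- mask
  one[, ] <- FALSE
  one[145:154, 200:320] <- TRUE
  expect_warning(place_measurement_points(one, disc, n_points = 2),
                 "one vessel")
})

test_that("end-to-end width recovery stays within tolerance across widths", {
  for (wv in list(c(4, 7), c(8, 12), c(14, 20))) {
    sp <- frame_phantom_spec(image_size = c(430, 360), disc_center = c(140, 170),
                             disc_radius = 32, artery_width = wv[1],
                             vein_width = wv[2], n_frames = 1,
                             motion_amplitude = 0, seed = 31)
    st <- render_frames(sp)
    res <- measure_frame(st$frames[[1]], truth_labels = st$truth$centerlines)
    got <- tapply(res$points$mean_width, res$points$vessel_label, median)
    expect_lt(abs(got[["artery"]] - wv[1]) / wv[1], 0.10)
    expect_lt(abs(got[["vein"]] - wv[2]) / wv[2], 0.10)
    av <- median(res$pairs$av_area)
    expect_lt(abs(av - (wv[1] / wv[2])^2) / (wv[1] / wv[2])^2, 0.15)
  }
})

test_that("doubling the resolution doubles widths but leaves the ratio fixed", {
  sp1 <- frame_phantom_spec(image_size = c(360, 300), disc_center = c(120, 140),
                            disc_radius = 25, artery_width = 5, vein_width = 8,
                            n_frames = 1, motion_amplitude = 0, seed = 13)
  sp2 <- frame_phantom_spec(image_size = c(720, 600), disc_center = c(240, 280),
                            disc_radius = 50, artery_width = 10, vein_width = 16,
                            n_frames = 1, motion_amplitude = 0, seed = 13)
  m1 <- measure_frame(render_frames(sp1)$frames[[1]],
                      truth_labels = render_frames(sp1)$truth$centerlines)
  m2 <- measure_frame(render_frames(sp2)$frames[[1]],
                      truth_labels = render_frames(sp2)$truth$centerlines)
  w1 <- tapply(m1$points$mean_width, m1$points$vessel_label, median)
  w2 <- tapply(m2$points$mean_width, m2$points$vessel_label, median)
  expect_lt(abs(w2[["vein"]] / w1[["vein"]] - 2), 0.2)
  expect_lt(abs(median(m2$pairs$av_area) - median(m1$pairs$av_area)), 0.06)
})
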