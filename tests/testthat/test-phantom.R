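test_that("rendering is bit-reproducible under a fixed seed", {
  sp <- small_phantom_spec(n_frames = 3, motion_amplitude = 2)
  a <- render_frames(sp)
  b <- render_frames(sp)
  expect_identical(a$frames, b$frames)
  expect_identical(a$info, b$info)
})

test_that("invalid phantom specs are rejected", {
  expect_error(small_phantom_spec(artery_width = 0.5), "unmeasurable")
  expect_error(frame_phantom_spec(image_size = c(100, 100),
                                  disc_center = c(10, 50), disc_radius = 30),
               "fully inside")
  expect_error(small_phantom_spec(fraction_nonfundus = 1))
})

test_that("ground truth records the drawn geometry and the area-ratio identity", {
  st <- small_stack()
  expect_equal(st$truth$av_area, (6 / 10)^2)
  expect_equal(st$truth$disc_center, c(120, 140))
  # the nominal 8/12 phantom forces av_area = 8^2/12^2
  sp <- frame_phantom_spec(image_size = c(400, 340), disc_center = c(140, 160),
                           disc_radius = 32, artery_width = 8, vein_width = 12,
                           n_frames = 1)
  expect_equal(render_frames(sp)$truth$av_area, 0.4444444, tolerance = 1e-6)
})

test_that("per-frame shifts stay within the motion amplitude and frame 1 is canonical", {
  sp <- small_phantom_spec(n_frames = 8, motion_amplitude = 3, seed = 21)
  st <- render_frames(sp)
  expect_true(all(abs(st$info$dx) <= 3 & abs(st$info$dy) <= 3))
  first_fundus <- which(st$info$is_fundus)[1]
  expect_identical(c(st$info$dx[first_fundus], st$info$dy[first_fundus]), c(0L, 0L))
})

test_that("noise/blur-free phantom profiles recover the drawn width on the true centerline", {
  sp <- small_phantom_spec(blur_sigma = 0, noise_sigma = 0)
  st <- render_frames(sp)
  f <- st$frames[[1]]
  for (v in c("artery", "vein")) {
    truth_w <- if (v == "artery") sp$artery_width else sp$vein_width
    cl <- st$truth$centerlines[[v]]
    mid <- cl[round(nrow(cl) * 0.6), ]
    cp <- crop_patch(f, mid)
    # ground-truth path expressed in patch coordinates
    loc <- cbind(cl[, 1] - cp$origin[1] + 1, cl[, 2] - cp$origin[2] + 1)
    keep <- loc[, 1] >= 10 & loc[, 1] <= 118 & loc[, 2] >= 10 & loc[, 2] <= 118
    loc <- loc[keep, , drop = FALSE]
    w <- perpendicular_widths(cp$patch, loc[seq(1, nrow(loc), by = 4), ])
    expect_lt(abs(median(w, na.rm = TRUE) - truth_w), 0.2)
  }
})

test_that("frame stacks round-trip through PNG + CSV + sidecar", {
  sp <- small_phantom_spec(n_frames = 3, motion_amplitude = 2,
                           fraction_nonfundus = 0.4, seed = 5)
  st <- render_frames(sp)
  dir <- withr::local_tempdir()
  write_frames(st, dir)
  expect_true(file.exists(file.path(dir, "frame_000001.png")))
  expect_true(file.exists(file.path(dir, "frames.csv")))
  back <- read_frames(dir)
  expect_equal(length(back$frames), 3)
  # 8-bit quantisation only
  expect_lt(max(abs(back$frames[[2]] - st$frames[[2]])), 1 / 255)
  expect_equal(back$info$is_fundus, st$info$is_fundus)
  expect_equal(back$truth$artery_width, st$truth$artery_width)
})

test_that("the truth mask covers the drawn vessels at the nominal width", {
  st <- small_stack()
  gt <- phantom_truth_mask(st)
  # area within 15% of the two rectangles' length x width outside the disc
  expect_gt(sum(gt), 1000)
  # every truth pixel is dark relative to background in the clean render
  sp <- small_phantom_spec(blur_sigma = 0, noise_sigma = 0)
  f <- render_frames(sp)$frames[[1]]
  expect_lt(max(f[gt]), 0.45)
})
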