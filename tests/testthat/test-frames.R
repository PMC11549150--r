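test_that("frame triage matches phantom ground truth and is deterministic", {
  sp <- frame_phantom_spec(image_size = c(320, 280), disc_center = c(110, 130),
                           disc_radius = 28, n_frames = 20,
                           fraction_nonfundus = 0.3, seed = 9)
  st <- render_frames(sp)
  cls <- vapply(st$frames, classify_frame, character(1))
  expect_identical(cls == "fundus", st$info$is_fundus)
  expect_identical(cls, vapply(st$frames, classify_frame, character(1)))
})

test_that("all-fundus phantoms classify as fundus; degenerate frames never error", {
  st <- small_stack()
  expect_identical(classify_frame(st$frames[[1]]), "fundus")
  expect_identical(classify_frame(matrix(0.5, 64, 64)), "no_fundus")
  set.seed(4)
  expect_identical(classify_frame(matrix(runif(64 * 64), 64, 64)), "no_fundus")
})

test_that("disc detection localises the phantom disc and refuses bad frames", {
  sp <- small_phantom_spec(noise_sigma = 0)
  st <- render_frames(sp)
  d <- detect_disc(st$frames[[1]])
  expect_false(is.null(d))
  expect_lt(sqrt(sum((d$center - sp$disc_center)^2)), 3)
  expect_lt(abs(d$radius - sp$disc_radius) / sp$disc_radius, 0.15)

  expect_null(detect_disc(matrix(0.5, 100, 100)))
  # disc straddling the border is rejected: downstream crops need it whole
  img <- matrix(0.4, 150, 150)
  xs <- matrix(seq_len(150), 150, 150, byrow = TRUE)
  ys <- matrix(seq_len(150), 150, 150)
  img[sqrt((xs - 2)^2 + (ys - 75)^2) < 30] <- 0.8
  expect_null(detect_disc(img))
})

test_that("the Tenengrad score matches a hand-evaluated Sobel oracle on a step edge", {
  # 21 x 21 frame, vertical step of height h at column 11; a disc spanning the
  # frame makes the 1.5x crop the full frame
  h_step <- 0.3
  img <- matrix(0, 21, 21)
  img[, 11:21] <- h_step
  disc <- list(center = c(11, 11), radius = 7)
  # interior pixels adjacent to the edge see gx = 4h, all else 0, gy = 0:
  # mean over the 19 x 19 interior = 2 * 19 * (4h)^2 / 19^2
  oracle <- 2 * 19 * (4 * h_step)^2 / 19^2
  expect_equal(tenengrad_score(img, disc), oracle, tolerance = 1e-12)
  # invariance to constant offset; zero for constant crops
  expect_equal(tenengrad_score(img + 0.17, disc), oracle, tolerance = 1e-12)
  expect_equal(tenengrad_score(matrix(0.6, 21, 21), disc), 0)
  expect_error(tenengrad_score(matrix(0.6, 21, 21), list(center = c(2, 2), radius = 0.3)),
               "degenerate")
})

test_that("Tenengrad decreases monotonically along a blur ladder", {
  sigmas <- c(0.4, 0.8, 1.6, 2.4, 3.2)
  scores <- vapply(sigmas, function(s) {
    st <- render_frames(small_phantom_spec(blur_sigma = s, noise_sigma = 0,
                                           seed = 3))
    f <- st$frames[[1]]
    tenengrad_score(f, detect_disc(f))
  }, numeric(1))
  expect_true(all(diff(scores) < 0))
})

test_that("reference selection picks the sharpest frame and breaks ties by time", {
  # graded blur across separately rendered frames, shuffled into one stack
  sigmas <- c(2.4, 0.4, 1.2, 3.0)
  frames <- lapply(sigmas, function(s) {
    render_frames(small_phantom_spec(blur_sigma = s, noise_sigma = 0.01,
                                     seed = 3))$frames[[1]]
  })
  stack <- list(frames = frames,
                info = tibble::tibble(frame_index = 1:4,
                                      timestamp_s = (0:3) / 15,
                                      is_fundus = TRUE, dx = 0L, dy = 0L))
  class(stack) <- "frame_stack"
  sel <- select_reference(stack)
  expect_equal(sel$reference, which.min(sigmas))
  expect_true(all(sel$triage$frame_class == "fundus"))

  # identical frames: the tie rule picks the earliest timestamp
  stack$frames <- rep(frames[2], 4)
  expect_equal(select_reference(stack)$reference, 1L)

  # no fundus frames at all -> session excluded
  noise <- replicate(3, matrix(runif(80 * 80), 80, 80), simplify = FALSE)
  bad <- structure(list(frames = noise,
                        info = tibble::tibble(frame_index = 1:3,
                                              timestamp_s = (0:2) / 15)),
                   class = "frame_stack")
  expect_error(select_reference(bad), "image quality")
})

test_that("cross-correlation registration recovers rigid shifts exactly", {
  sp <- small_phantom_spec(n_frames = 6, motion_amplitude = 4, noise_sigma = 0,
                           seed = 5)
  st <- render_frames(sp)
  ref <- st$frames[[1]]
  for (i in 2:6) {
    al <- align_to_reference(st$frames[[i]], ref)
    expect_true(al$ok)
    # recovered shift undoes the rendered motion
    expect_identical(c(al$dx, al$dy), -c(st$info$dx[i], st$info$dy[i]))
    expect_equal(al$aligned[20:280, 20:340], ref[20:280, 20:340],
                 tolerance = 1e-12)
  }
  # self-alignment is the zero shift
  self <- align_to_reference(ref, ref)
  expect_identical(c(self$dx, self$dy), c(0L, 0L))
  # uncorrelated noise fails the correlation gate
  set.seed(2)
  a <- matrix(runif(300 * 360), 300)
  b <- matrix(runif(300 * 360), 300)
  expect_false(align_to_reference(a, b)$ok)
})

test_that("triage_frames reports every exclusion with a reason", {
  sp <- frame_phantom_spec(image_size = c(320, 280), disc_center = c(110, 130),
                           disc_radius = 28, n_frames = 10,
                           fraction_nonfundus = 0.3, motion_amplitude = 2,
                           seed = 9)
  st <- render_frames(sp)
  tri <- triage_frames(st)
  expect_equal(nrow(tri$report), 10)
  expect_true(all(tri$report$reason[!tri$report$included] %in%
                    c("no_fundus", "unaligned")))
  expect_identical(tri$report$included,
                   tri$report$frame_class == "fundus" &
                     tri$report$reason == "included")
  expect_true(st$info$is_fundus[tri$reference])
})
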