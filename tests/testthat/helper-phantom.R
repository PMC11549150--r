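# Shared fixtures, built in code and cached per test run.

.fixtures <- new.env(parent = emptyenv())

# Small, fast phantom used by most image tests.
small_phantom_spec <- function(...) {
  args <- utils::modifyList(
    list(image_size = c(360, 300), disc_center = c(120, 140), disc_radius = 30,
         artery_width = 6, vein_width = 10, n_frames = 1, motion_amplitude = 0,
         blur_sigma = 0.8, noise_sigma = 0.02, seed = 7),
    list(...)
  )
  do.call(frame_phantom_spec, args)
}

cached_stack <- function(key, spec) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- render_frames(spec)
  .fixtures[[key]]
}

small_stack <- function() cached_stack("small", small_phantom_spec())

# Soft (anti-aliased) bar mask through the patch centre at a given angle:
# pixel value = coverage ramp whose half-level sits exactly at distance
# width/2 from the bar axis.
soft_bar_patch <- function(size = 128, width = 12, angle = 0) {
  cx <- (size + 1) / 2
  nx <- -sin(angle); ny <- cos(angle)  # unit normal to the bar axis
  xs <- matrix(seq_len(size), size, size, byrow = TRUE)
  ys <- matrix(seq_len(size), size, size)
  d <- abs((xs - cx) * nx + (ys - cx) * ny)
  pmin(pmax(width / 2 + 0.5 - d, 0), 1)
}

# Independent rank-based AUC oracle: pairwise comparison probability with
# half-credit for ties (positives have LOWER scores here).
auc_bruteforce <- function(score, is_case) {
  cases <- score[is_case]; controls <- score[!is_case]
  tot <- 0
  for (x in cases) tot <- tot + sum(x < controls) + 0.5 * sum(x == controls)
  tot / (length(cases) * length(controls))
}
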