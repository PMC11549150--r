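test_that("stratified fits recover the generating slopes", {
  coh <- generate_cohort(cohort_spec(seed = 11))
  hi <- fit_stratum(coh, "icp_gt_15")
  expect_lt(abs(hi$slope - (-0.0659)), 1.96 * hi$se)
  expect_lt(hi$p, 0.001)
  lo <- fit_stratum(coh, "icp_le_15")
  expect_true(lo$ci95[1] <= 0 && 0 <= lo$ci95[2])
  # CI identity: slope +/- 1.96 SE, exactly
  expect_identical(hi$ci95, c(hi$slope - 1.96 * hi$se, hi$slope + 1.96 * hi$se))
  expect_equal(hi$n_patients, 15)

  td <- tidy(hi)
  expect_equal(td$estimate, hi$slope)
  expect_equal(glance(hi)$nobs, hi$n_obs)
})

test_that("a noise-free linear cohort is fit to machine precision", {
  s <- cohort_spec(n_patients = 3, points_per_session = 30,
                   baseline_av_sd = 0, residual_sd = 0,
                   slope_above = -0.02, slope_below = -0.02)
  coh <- generate_cohort(s)
  f <- suppressWarnings(fit_stratum(coh, "icp_le_15"))
  expect_equal(f$slope, -0.02, tolerance = 1e-10)
})

test_that("unfittable strata fail loudly, naming the stratum", {
  coh <- generate_cohort(cohort_spec(n_patients = 3, points_per_session = 10))
  solo <- dplyr::filter(coh, patient_id == "P01")
  expect_error(fit_stratum(solo, "icp_le_15"), "icp_le_15")
  no_iop <- dplyr::mutate(coh, iop_mmhg = NA_real_)
  expect_error(fit_stratum(no_iop, "icp_gt_iop"), "icp_gt_iop")
  w <- capture_warnings(tab <- fit_all_strata(no_iop, icp_threshold = 15))
  expect_true(any(grepl("icp_gt_iop", w)))
  expect_true(any(grepl("icp_le_iop", w)))
  expect_setequal(tab$stratum, c("icp_gt_15", "icp_le_15"))
})

test_that("slope comparison satisfies the pooled-SE and CI identities exactly", {
  set.seed(99)
  for (i in 1:20) {
    s1 <- rnorm(1); e1 <- runif(1, 1e-4, 1e-2)
    s2 <- rnorm(1); e2 <- runif(1, 1e-4, 1e-2)
    cmp <- compare_slopes(c(s1, e1), c(s2, e2))
    expect_identical(cmp$diff, s1 - s2)
    expect_identical(cmp$se_diff, sqrt(e1^2 + e2^2))
    expect_identical(cmp$z, cmp$diff / cmp$se_diff)
    expect_identical(cmp$ci95,
                     c(cmp$diff - 1.96 * cmp$se_diff, cmp$diff + 1.96 * cmp$se_diff))
  }
  ident <- compare_slopes(c(-0.01, 2e-4), c(-0.01, 2e-4))
  expect_equal(ident$diff, 0)
  expect_equal(ident$p, 1)
  expect_error(compare_slopes(c(1, 0), c(2, 0)), "undefined")
})

test_that("ICC tracks the generating variance ratio and hits its limits", {
  # preset rho = 0.6: baseline_sd^2 / (baseline_sd^2 + residual_sd^2)
  rho <- 0.6
  res_sd <- 0.08
  b_sd <- res_sd * sqrt(rho / (1 - rho))
  # ~20 patients keeps the Monte-Carlo SD of the mean ICC near 0.03, so a
  # 0.1 band is a genuine recovery check rather than a coin flip
  iccs <- vapply(1:6, function(s) {
    coh <- generate_cohort(cohort_spec(n_patients = 20, sessions_per_patient = 1,
                                       points_per_session = 300,
                                       baseline_av_sd = b_sd,
                                       residual_sd = res_sd, seed = 100 + s))
    model_summary(coh)$icc
  }, numeric(1))
  expect_lt(abs(mean(iccs) - rho), 0.1)

  # residual-free limit -> ICC ~ 1; baseline-free limit -> ICC ~ 0
  hi <- generate_cohort(cohort_spec(n_patients = 6, points_per_session = 50,
                                    baseline_av_sd = 0.1, residual_sd = 1e-4))
  expect_gt(suppressWarnings(model_summary(hi))$icc, 0.99)
  lo <- generate_cohort(cohort_spec(n_patients = 6, points_per_session = 50,
                                    baseline_av_sd = 0, residual_sd = 0.1))
  expect_lt(suppressWarnings(model_summary(lo))$icc, 0.02)
})

test_that("model summary reports finite fit statistics on the default cohort", {
  coh <- generate_cohort(cohort_spec(seed = 19))
  ms <- model_summary(coh)
  expect_true(ms$icc > 0 && ms$icc < 1)
  expect_true(ms$r_squared > 0 && ms$r_squared <= 1)
  expect_gt(ms$f_stat, 0)
  g <- glance(ms)
  expect_equal(g$icc, ms$icc)
  expect_equal(nrow(tidy(ms)), 3)  # intercept + two spline terms
})

test_that("diagnostics reproduce the confusion identities on toy data", {
  toy <- tibble::tibble(
    patient_id = "P", av_ratio = c(rep(0.5, 40), rep(1.0, 60)),
    icp_mmhg = c(rep(20, 40), rep(10, 60))
  )
  d <- diagnostics(toy, cutoff = 0.75)
  expect_equal(d$sensitivity, 1)
  expect_equal(d$specificity, 1)
  expect_equal(d$auc, 1)
  expect_equal(unname(d$confusion), c(40, 0, 60, 0))

  one_class <- dplyr::mutate(toy, icp_mmhg = 10)
  expect_error(diagnostics(one_class), "both ICP classes")
})

test_that("AUC equals the brute-force pairwise probability and is monotone-invariant", {
  set.seed(5)
  obs <- tibble::tibble(
    patient_id = "P",
    av_ratio = round(runif(150, 0.4, 1.2), 2),  # rounding forces ties
    icp_mmhg = sample(c(10, 20), 150, replace = TRUE)
  )
  d <- diagnostics(obs)
  expect_equal(d$auc, auc_bruteforce(obs$av_ratio, obs$icp_mmhg > 15),
               tolerance = 1e-12)
  # strictly monotone transform of the ratio leaves the AUC unchanged
  obs2 <- dplyr::mutate(obs, av_ratio = av_ratio^3)
  expect_equal(diagnostics(obs2)$auc, d$auc, tolerance = 1e-12)

  # random labels at larger n -> AUC near 1/2
  set.seed(6)
  null_obs <- tibble::tibble(patient_id = "P", av_ratio = runif(3000),
                             icp_mmhg = sample(c(10, 20), 3000, replace = TRUE))
  expect_lt(abs(diagnostics(null_obs)$auc - 0.5), 0.04)
})

test_that("implied NPV solves the prevalence identity", {
  sym <- implied_npv(0.5, 0.5, 0.5)
  expect_equal(sym$prevalence, 0.5)
  expect_equal(sym$npv, 0.5)

  perfect <- implied_npv(1, 1, 1)
  expect_equal(perfect$npv, 1)

  # independent grid-search oracle for a generic case
  sens <- 0.8008; spec <- 0.2251; ppv <- 0.757
  grid <- seq(1e-4, 1 - 1e-4, by = 1e-4)
  ppv_grid <- sens * grid / (sens * grid + (1 - spec) * (1 - grid))
  pi_star <- grid[which.min(abs(ppv_grid - ppv))]
  got <- implied_npv(sens, spec, ppv)
  expect_lt(abs(got$prevalence - pi_star), 2e-4)
  npv_star <- spec * (1 - pi_star) / (spec * (1 - pi_star) + (1 - sens) * pi_star)
  expect_lt(abs(got$npv - npv_star), 1e-3)

  # perfect specificity forces PPV = 1; anything less is contradictory
  expect_error(implied_npv(0.5, 1, 0.5), "inconsistent")
})
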