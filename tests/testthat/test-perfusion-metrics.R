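make_noiseless <- function(fmax, tmax, t_half, dt = 1, baseline = 5,
                           t_onset = 10, record_length = 400) {
  gamma_curve(calibrate_gamma(fmax, tmax, t_half, baseline = baseline,
                              t_onset = t_onset),
              dt = dt, record_length = record_length)
}

test_that("smoothing is the identity for window 1 and for constant curves", {
  cv <- tibble::tibble(time_s = 0:19, intensity_au = sin(0:19))
  expect_equal(smooth_curve(cv, window = 1), cv)
  const <- tibble::tibble(time_s = 0:19, intensity_au = rep(4, 20))
  expect_equal(smooth_curve(const, window = 5), const)
  expect_error(smooth_curve(cv, window = 4), class = "icg_validation_error")
})

test_that("smoothing equals a naive per-point window mean", {
  set.seed(601)
  cv <- tibble::tibble(time_s = 0:49, intensity_au = rnorm(50))
  sm <- smooth_curve(cv, window = 5)
  expect_equal(sm$intensity_au, naive_moving_average(cv$intensity_au, 5))
  sm7 <- smooth_curve(cv, window = 7)
  expect_equal(sm7$intensity_au, naive_moving_average(cv$intensity_au, 7))
})

test_that("curve validation rejects malformed input", {
  expect_error(validate_curve(data.frame(a = 1:10)),
               class = "icg_validation_error")
  expect_error(validate_curve(tibble::tibble(time_s = c(1:5, 5, 7:10),
                                             intensity_au = rep(1, 10))),
               class = "icg_validation_error")
  expect_error(validate_curve(tibble::tibble(time_s = 1:10,
                                             intensity_au = c(rep(1, 9), NA))),
               class = "icg_validation_error")
  expect_error(validate_curve(tibble::tibble(time_s = 1:5,
                                             intensity_au = 1:5)),
               class = "icg_validation_error")
})

test_that("onset is recovered within one sampling interval on noiseless curves", {
  for (dt in c(1, 0.5)) {
    cv <- make_noiseless(176, 192, 8.8, dt = dt)
    det <- detect_onset(cv)
    expect_lt(abs(det$t_onset - 10), dt + 1e-9)
    expect_equal(det$baseline, 5, tolerance = 1e-9)
  }
  # slow-rising severe-ischemia curve
  cv3 <- make_noiseless(64, 230, 76.9)
  expect_lt(abs(detect_onset(cv3)$t_onset - 10), 1 + 1e-9)
})

test_that("a flat noise-only record raises a no-signal error carrying the threshold", {
  set.seed(602)
  cv <- tibble::tibble(time_s = 0:199, intensity_au = rnorm(200, 5, 0.5))
  err <- tryCatch(detect_onset(cv), error = identity)
  expect_s3_class(err, "icg_no_signal")
  expect_true(is.finite(err$threshold))
})

test_that("onset error stays small under acquisition noise", {
  g <- study_groups(cv = 0)[1, ]
  g$n <- 100L
  coh <- simulate_cohort(g, noise_spec(additive_sd_frac = 0.02,
                                       sampling_dt = 1), seed = 603)
  onsets <- vapply(coh$curve, function(cv) detect_onset(cv)$t_onset,
                   numeric(1))
  expect_lte(median(abs(onsets - 10)), 2)   # two sampling intervals
})

test_that("a linear ramp yields the closed-form parameter set", {
  cv <- tibble::tibble(time_s = 0:200,
                       intensity_au = c(0:100, rep(100, 100)))
  p <- extract_parameters(cv, cfg = extraction_config(smooth_window = 1),
                          baseline = 0, t_onset = 0)
  expect_equal(p$fmax, 100)
  expect_equal(p$tmax, 100)
  expect_equal(p$t_half, 50)
  expect_equal(p$slope, 1)
  expect_equal(p$tr, 0.5)
})

test_that("noiseless calibrated curves reproduce their targets within 1 percent", {
  targets <- list(c(176, 192, 8.8), c(101, 172, 18.7),
                  c(91, 208, 35.1), c(64, 230, 76.9))
  for (tg in targets) {
    cv <- make_noiseless(tg[1], tg[2], tg[3], dt = 0.5)
    p <- extract_parameters(cv)
    expect_lt(abs(p$fmax - tg[1]) / tg[1], 0.01)
    expect_lt(abs(p$tmax - tg[2]) / tg[2], 0.01)
    expect_lt(abs(p$t_half - tg[3]) / tg[3], 0.01)
    expect_lt(abs(p$slope - tg[1] / tg[2]) / (tg[1] / tg[2]), 0.01)
  }
})

test_that("the interpolated half-crossing matches a dense resampling oracle", {
  spec <- calibrate_gamma(91, 208, 35.1)
  cv <- gamma_curve(spec, dt = 1)
  p <- extract_parameters(cv)
  dense <- grid_half_time(spec, n_grid = 1e4)
  expect_lt(abs(p$t_half - dense), spec$t_peak_offset / 1e4 + 0.05)
})

test_that("slope and TR identities hold to machine precision", {
  set.seed(604)
  coh <- simulate_cohort(study_groups(cv = 0.1), noise_spec(0.02), seed = 605)
  params <- extract_cohort_parameters(coh)
  expect_equal(params$slope * params$tmax, params$fmax, tolerance = 1e-12)
  expect_equal(params$tr * params$tmax, params$t_half, tolerance = 1e-12)
  expect_true(all(params$tr > 0 & params$tr <= 1))
})

test_that("extraction is equivariant under intensity scaling and time shifts", {
  set.seed(606)
  spec <- calibrate_gamma(101, 172, 18.7)
  cv <- gamma_curve(spec, dt = 1)
  cv$intensity_au <- cv$intensity_au + rnorm(nrow(cv), 0, 2)
  p <- extract_parameters(cv)

  scaled <- cv
  scaled$intensity_au <- cv$intensity_au * 3.7
  ps <- extract_parameters(scaled)
  expect_equal(ps$fmax, 3.7 * p$fmax, tolerance = 1e-9)
  expect_equal(ps$slope, 3.7 * p$slope, tolerance = 1e-9)
  expect_equal(ps$tmax, p$tmax, tolerance = 1e-9)
  expect_equal(ps$t_half, p$t_half, tolerance = 1e-9)
  expect_equal(ps$tr, p$tr, tolerance = 1e-9)

  shifted <- cv
  shifted$time_s <- cv$time_s + 37
  pt <- extract_parameters(shifted)
  expect_equal(pt$t_onset, p$t_onset + 37, tolerance = 1e-9)
  expect_equal(pt$fmax, p$fmax, tolerance = 1e-9)
  expect_equal(pt$tmax, p$tmax, tolerance = 1e-9)
  expect_equal(pt$t_half, p$t_half, tolerance = 1e-9)
})

test_that("parameter ordering tracks ischemia severity on noiseless group curves", {
  g <- study_groups()
  params <- purrr::map_dfr(seq_len(4), function(k) {
    extract_parameters(make_noiseless(g$target_fmax[k], g$target_tmax[k],
                                      g$target_t_half[k], dt = 0.5))
  })
  expect_true(all(diff(params$slope) < 0))   # slope falls with severity
  expect_true(all(diff(params$t_half) > 0))  # rise time stretches
  expect_true(all(diff(params$fmax) < 0))
})

test_that("quality flags fire on truncated peaks and weak signals", {
  # record ends before the peak
  cv <- gamma_curve(calibrate_gamma(100, 300, 60), dt = 1,
                    record_length = 250)
  p <- extract_parameters(cv)
  expect_true(p$flag_max_at_end)

  # deterministic weak record: baseline variability sd ~1, plateau only 4 AU
  # above baseline, so fmax sits between the detection (3 sd) and quality
  # (5 sd) thresholds
  weak <- tibble::tibble(
    time_s = 0:299,
    intensity_au = c(rep(c(4, 6), 75), 5 + seq(0.4, 4, by = 0.4),
                     rep(9, 140)))
  pw <- extract_parameters(weak)
  expect_true(pw$flag_weak_signal)
})

test_that("reporting precision rounds without touching internal values", {
  p <- extract_parameters(make_noiseless(176, 192, 8.8, dt = 0.5))
  f <- format_parameters(p)
  expect_equal(f$fmax, round(p$fmax))
  expect_equal(f$tmax, round(p$tmax, 1))
  expect_equal(f$slope, round(p$slope, 2))
  expect_equal(f$tr, round(p$tr, 3))
})
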