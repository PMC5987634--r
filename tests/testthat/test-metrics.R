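test_that("peak-to-peak amplitude behaves as max minus min", {
  expect_equal(peak_to_peak(rep(2, 10)), 0)
  expect_equal(peak_to_peak(c(-3, 1, 0.5)), 4)
  t <- seq(0, 1, by = 1e-4)
  expect_equal(peak_to_peak(3 * sin(2 * pi * 5 * t)), 6, tolerance = 1e-3)
  expect_equal(peak_to_peak(rev(c(-3, 1, 0.5))), 4)   # time reversal
  expect_error(peak_to_peak(1), "2 samples")
})

test_that("half-amplitude width matches closed forms for simple shapes", {
  # symmetric triangle of base width w and baseline 0: half width = w / 2
  t <- seq(0, 10, by = 0.001)
  w <- 4
  tri <- pmax(0, 1 - abs(t - 5) / (w / 2))
  expect_equal(width_at_half_amplitude(tri, t), w / 2, tolerance = 1e-3)
  # Gaussian pulse: FWHM = 2 sigma sqrt(2 log 2)
  sg <- 0.7
  gauss <- exp(-(t - 5)^2 / (2 * sg^2))
  expect_equal(width_at_half_amplitude(gauss, t),
               2 * sg * sqrt(2 * log(2)), tolerance = 1e-3)
  # time translation leaves the width unchanged
  expect_equal(width_at_half_amplitude(gauss, t + 13),
               width_at_half_amplitude(gauss, t), tolerance = 1e-12)
})

test_that("time-rescaling a biphasic waveform rescales its width exactly", {
  wf <- make_biphasic_waveform(vpp = 80, width = 0.5, dt = 0.002)
  w1 <- width_at_half_amplitude(wf$trace, wf$time)
  c_factor <- 1.7
  w2 <- width_at_half_amplitude(wf$trace, wf$time * c_factor)
  expect_equal(w2 / w1, c_factor, tolerance = 1e-9)
})

test_that("uncrossed thresholds give an error, not a truncated width", {
  t <- seq(0, 1, by = 0.01)
  expect_error(width_at_half_amplitude(t, t), "never crossed")
})

test_that("initial positivity detection follows its definition", {
  t <- seq(0, 10, by = 0.01)
  spike <- -exp(-(t - 5)^2 / 0.08)
  expect_false(detect_initial_positivity(spike, t)$detected)
  bump <- spike + 0.2 * exp(-(t - 4)^2 / 0.05)
  det <- detect_initial_positivity(bump, t)
  expect_true(det$detected)
  expect_lt(det$time, 5)
  expect_false(detect_initial_positivity(rep(0, 11), t[1:11])$detected)
  # sub-threshold bumps are ignored
  faint <- spike + 0.02 * exp(-(t - 4)^2 / 0.05)
  expect_false(detect_initial_positivity(faint, t)$detected)
})

test_that("power-law fits recover planted exponents", {
  prof <- make_powerlaw_profile(k = -2, n_points = 15)
  fit <- fit_power_law(prof$distances, prof$amplitudes,
                       fit_range = range(prof$distances))
  expect_equal(fit$k, -2, tolerance = 1e-12)
  prof1 <- make_powerlaw_profile(k = -1, n_points = 15)
  expect_equal(fit_power_law(prof1$distances, prof1$amplitudes,
                             fit_range = range(prof1$distances))$k,
               -1, tolerance = 1e-12)
  # noiseless bias across the physically relevant exponent range
  for (k in seq(-3, -1, by = 0.5)) {
    p <- make_powerlaw_profile(k = k, n_points = 10)
    f <- fit_power_law(p$distances, p$amplitudes,
                       fit_range = range(p$distances))
    expect_lt(abs(f$k - k), 0.01)
  }
})

test_that("noisy power-law fits stay within their standard errors", {
  prof <- make_powerlaw_profile(k = -2, n_points = 20, noise_sd = 0.05,
                                seed = 7)
  fit <- fit_power_law(prof$distances, prof$amplitudes,
                       fit_range = range(prof$distances))
  expect_lt(abs(fit$k + 2), 3 * fit$stderr_k)
  expect_equal(fit$n_points, 20)
})

test_that("power-law fit rejects invalid inputs", {
  expect_error(fit_power_law(c(-1, 2, 3), c(1, 2, 3)), "> 0")
  expect_error(fit_power_law(c(10, 20, 400), c(1, 2, 3),
                             fit_range = c(1, 30)), "fewer than 3")
})

test_that("phase plots have the closed-form geometry of a sine wave", {
  dt <- 1e-3
  t <- seq(0, 2, by = dt)
  om <- 2 * pi * 3
  pp <- phase_plot(2 * sin(om * t), dt)
  expect_equal(max(pp$dVdt), 2 * om, tolerance = 1e-3)
  expect_true(all(abs(phase_plot(rep(1, 100), dt)$dVdt) < 1e-12))
  expect_error(phase_plot(c(1, 2), dt), "3 samples")
})

test_that("onset rapidity separates abrupt from gradual upstrokes", {
  dt <- 0.005
  t <- seq(0, 10, by = dt)
  smooth <- -70 + 90 / (1 + exp(-(t - 5) / 0.4))      # gradual sigmoid
  kinked <- -70 + ifelse(t < 5, 1 * (t / 5),           # flat approach ...
                         pmin(90, 300 * (t - 5)))      # ... then abrupt rise
  expect_gt(onset_rapidity(kinked, dt, at_dvdt = 10),
            5 * onset_rapidity(smooth, dt, at_dvdt = 10))
})
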