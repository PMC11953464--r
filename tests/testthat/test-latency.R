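test_that("latency metrics recover analytic peak, onset and FWHM", {
  h <- hrf_params(p1 = 5, f1 = 4, dip = 0)
  curve <- fitted_curve(function(t) eval_hrf(h, t), c(0, 25),
                        "double_gamma")
  m <- latency_metrics(curve)
  expect_equal(m$peak_s, 5, tolerance = 1e-3)
  expect_equal(m$peak_amplitude, 1, tolerance = 1e-4)
  # independent onset oracle: bisection on the analytic form before peak
  onset_true <- uniroot(function(t) eval_hrf(h, t) - 0.1,
                        c(1e-6, 5), tol = 1e-10)$root
  expect_equal(m$onset_s, onset_true, tolerance = 1e-2)
  # scaling the curve leaves all latencies unchanged
  m3 <- latency_metrics(fitted_curve(function(t) 3 * eval_hrf(h, t),
                                     c(0, 25), "double_gamma"))
  expect_equal(m3$peak_s, m$peak_s, tolerance = 1e-6)
  expect_equal(m3$onset_s, m$onset_s, tolerance = 1e-6)
  expect_equal(m3$fwhm_s, m$fwhm_s, tolerance = 1e-6)
  expect_equal(m3$peak_amplitude, 3 * m$peak_amplitude, tolerance = 1e-4)
})

test_that("shifting a curve shifts onset and peak by exactly that amount", {
  h <- hrf_params(dip = 0)
  delta <- 0.83
  m0 <- latency_metrics(fitted_curve(function(t) eval_hrf(h, t),
                                     c(0, 25), "double_gamma"))
  m1 <- latency_metrics(fitted_curve(function(t) eval_hrf(h, t - delta),
                                     c(0, 25), "double_gamma"))
  expect_equal(m1$peak_s - m0$peak_s, delta, tolerance = 1e-3)
  expect_equal(m1$onset_s - m0$onset_s, delta, tolerance = 1e-2)
  expect_equal(m1$fwhm_s, m0$fwhm_s, tolerance = 1e-3)
})

test_that("curves with no positive excursion are flagged undefined", {
  flat <- fitted_curve(function(t) rep(-1, length(t)), c(0, 10), "interp")
  m <- latency_metrics(flat)
  expect_false(m$defined)
  expect_true(is.na(m$peak_s))
})

test_that("smoothing spline fits noiseless curves closely and smooths
           more under noise", {
  tg <- seq(0, 13.5, by = 0.199)
  y <- eval_hrf(hrf_params(), tg)
  f <- fit_spline(tg, y)
  expect_lt(sqrt(mean((f$evaluator(tg) - y)^2)) / max(abs(y)), 0.01)
  cf <- fit_spline(tg, rep(2.5, length(tg)))
  expect_equal(cf$evaluator(c(1, 7)), c(2.5, 2.5))
  set.seed(7)
  f_noisy <- fit_spline(tg, y + rnorm(length(tg), 0, 0.3))
  expect_gt(f_noisy$params$lambda, f$params$lambda)
})

test_that("single-gamma fit recovers baseline-anchored bumps", {
  tg <- seq(0, 13.5, by = 0.199)
  truth <- 0.125 + 0.4 * eval_hrf(hrf_params(p1 = 6, f1 = 4, dip = 0), tg)
  f <- fit_single_gamma(tg, truth, baseline = 0.125)
  expect_lt(abs(f$params$A - 0.4) / 0.4, 0.05)
  expect_lt(abs(f$params$p - 6) / 6, 0.05)
  expect_lt(abs(f$params$f - 4) / 4, 0.05)
  # all-baseline input
  f0 <- fit_single_gamma(tg, rep(0.125, length(tg)), baseline = 0.125)
  expect_lt(abs(f0$params$A), 1e-4)
  # time-shifted input shifts the fitted time-to-peak by the same amount
  shifted <- 0.125 + 0.4 * eval_hrf(hrf_params(p1 = 6, f1 = 4, dip = 0),
                                    tg - 1.0)
  fs <- fit_single_gamma(tg, shifted, baseline = 0.125)
  m0 <- latency_metrics(f); ms <- latency_metrics(fs)
  expect_equal(ms$peak_s - m0$peak_s, 1.0, tolerance = 0.1)
})

test_that("the tied-width paired gamma fit recovers a known temporal
           shift between two noisy curves", {
  set.seed(77)
  tg <- seq(0, 13.5, by = 0.199)
  g <- function(t, p) eval_hrf(hrf_params(p1 = p, f1 = 4, dip = 0),
                               pmax(t, 0))
  y1 <- 0.125 + 0.35 * g(tg, 5) + rnorm(length(tg), 0, 0.02)
  y2 <- 0.125 + 0.30 * g(tg - 0.55, 5) + rnorm(length(tg), 0, 0.02)
  pair <- fit_gamma_pair(tg, y1, tg, y2, 0.125)
  expect_lt(abs(pair$shift - 0.55), 0.15)
  expect_lt(abs(pair$A1 - 0.35), 0.05)
  expect_lt(abs(pair$A2 - 0.30), 0.05)
  # the two fitted curves share their width
  expect_equal(pair$curve1$params$f, pair$curve2$params$f)
})

test_that("second-task alignment shifts follow the floor rule for raw
           data and are exact for fitted curves", {
  expect_equal(soa_shift(1.5, 0.199, "raw"), 1.393)
  expect_equal(soa_shift(0.3, 0.199, "raw"), 0.199)
  expect_equal(soa_shift(1.5, 0.199, "fitted"), 1.5)
  expect_equal(soa_shift(0.3, 0.199, "fitted"), 0.3)
  expect_equal(soa_shift(0, 0.199, "raw"), 0)
  tc <- list(time = seq(0, 2, by = 0.199), values = rnorm(11))
  sh <- shift_timecourse(tc, 0.3, 0.199, "raw")
  expect_equal(attr(sh, "shift"), 0.199)
  expect_equal(sh$time, tc$time - 0.199)
  id <- shift_timecourse(tc, 0, 0.199, "fitted")
  expect_equal(id$time, tc$time)
})
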