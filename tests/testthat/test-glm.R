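make_run <- function(data, tr = 0.199) bold_run(data, tr)

test_that("percent-signal scaling normalizes every voxel mean to 100", {
  X <- cbind(rep(500, 50), 90 + 20 * runif(50), rnorm(50, 1000, 5))
  run <- make_run(X)
  sc <- scale_percent(run)
  expect_equal(unique(round(sc$data[, 1], 10)), 100)
  expect_equal(colMeans(sc$data), rep(100, 3), ignore_attr = TRUE)
  # idempotent: scaling a scaled run changes nothing
  sc2 <- scale_percent(sc)
  expect_equal(sc2$data, sc$data)
  # multiplying raw data by a constant leaves the scaled data unchanged
  sc3 <- scale_percent(make_run(X * 7.3))
  expect_equal(sc3$data, sc$data)
  # a zero-mean voxel is flagged and excluded
  bad <- make_run(cbind(X[, 1], 0 * X[, 1]))
  expect_warning(scb <- scale_percent(bad), "excluded")
  expect_equal(ncol(scb$data), 1)
  expect_equal(attr(scb, "excluded"), 2L)
})

test_that("FIR basis columns are per-lag indicators that sum over
           overlapping trials", {
  tr <- 0.199
  X <- build_fir_basis(0, 5, tr, 50)
  expect_equal(dim(X), c(50, 5))
  expect_equal(which(X[, 1] == 1), 1L)
  expect_equal(which(X[, 3] == 1), 3L)
  X69 <- build_fir_basis(c(2, 6) * tr, 69, tr, 200)
  expect_equal(ncol(X69), 69)
  # overlapping windows add
  Xo <- build_fir_basis(c(0, 2 * tr), 5, tr, 20)
  expect_equal(Xo[3, 1], 1)
  expect_equal(Xo[3, 3], 1)
  expect_equal(max(build_fir_basis(c(0, 0), 3, tr, 10)), 2)
  expect_warning(build_fir_basis(9 * tr, 5, tr, 10), "truncated")
})

test_that("FIR deconvolution recovers arbitrary lag profiles exactly on
           noiseless data", {
  set.seed(20)
  tr <- 0.199
  onsets <- c(5, 40, 90, 130) * tr
  h <- rnorm(20)
  X <- build_fir_basis(onsets, 20, tr, 200)
  y <- X %*% h + 7
  fit <- fit_glm_prewhitened(cbind(y), cbind(X, 1))
  expect_equal(drop(fit$betas[1:20, 1]), h, tolerance = 1e-9)
})

test_that("whole-event regressors superpose and track the HRF", {
  tr <- 0.199; n <- 400
  h <- hrf_params()
  r1 <- build_event_regressor(0, h, tr, n)
  nk <- 140  # within the sampled kernel's support
  expect_equal(r1[1:nk], eval_hrf(h, (0:(nk - 1)) * tr),
               tolerance = 1e-12)
  r2 <- build_event_regressor(50 * tr, h, tr, n)
  r12 <- build_event_regressor(c(0, 50 * tr), h, tr, n)
  expect_equal(r12, r1 + r2, tolerance = 1e-12)
  # compound (longer p1) events peak later
  slow <- build_event_regressor(0, hrf_params(p1 = 8), tr, n)
  expect_gt(which.max(slow), which.max(r1))
})

test_that("prewhitened GLS matches OLS for white noise and recovers
           betas and the AR coefficient under AR(1) noise", {
  set.seed(21)
  n <- 800
  X <- cbind(1, rnorm(n), rnorm(n))
  B <- c(2, 0.5, -1)
  yw <- X %*% B + rnorm(n)
  fw <- fit_glm_prewhitened(cbind(yw), X, ar_pool = "voxel")
  ols <- qr.coef(qr(X), yw)
  expect_equal(drop(fw$betas), drop(ols), tolerance = 0.02)
  Y <- sapply(1:4, function(i)
    X %*% B + as.numeric(arima.sim(list(ar = 0.5), n)))
  fa <- fit_glm_prewhitened(Y, X, ar_pool = "voxel")
  expect_lt(max(abs(fa$ar_coeff - 0.5)), 0.12)
  expect_lt(max(abs(fa$betas - B)), 0.25)
  # t statistics for a simple contrast are finite and reasonable
  fc <- fit_glm_prewhitened(Y, X, contrasts = rbind(c(0, 1, 0)))
  expect_true(all(is.finite(fc$tstats)))
  expect_true(all(fc$tstats > 3))
})

test_that("censoring equals fitting the row-deleted system and removes
           outlier influence", {
  set.seed(22)
  n <- 300
  X <- cbind(1, rnorm(n))
  y <- X %*% c(1, 2) + rnorm(n, 0, 0.5)
  keep <- rep(TRUE, n); keep[c(20, 120, 121)] <- FALSE
  f1 <- fit_glm_prewhitened(cbind(y), X, censor = keep)
  f2 <- fit_glm_prewhitened(cbind(y[keep]), X[keep, ])
  expect_equal(f1$betas, f2$betas)
  expect_equal(f1$sigma2, f2$sigma2)
  # spiking the censored rows does not change the estimates
  y_sp <- y; y_sp[!keep] <- 1e4
  f3 <- fit_glm_prewhitened(cbind(y_sp), X, censor = keep)
  expect_equal(f3$betas, f1$betas)
})

test_that("rank-deficient designs fail loudly, naming columns", {
  X <- cbind(a = rep(1, 50), b = rnorm(50))
  X <- cbind(X, c = X[, "a"] + X[, "b"])
  expect_error(fit_glm_prewhitened(cbind(rnorm(50)), X), "collinear")
})

test_that("condition timecourses recover the generative ROI-mean response
           on noiseless data", {
  set.seed(23)
  spec <- tiny_spec(trials_per_run = 18, run_volumes = 1000)
  d <- det_trials(spec)
  reg <- region_model("auditory", 4, pattern_gain = 0,
                      sensory_dur = 3 * spec$tr,  # grid-exact boxcar
                      hrf = hrf_params(dip = 0))  # response dies inside
                                                  # the FIR window
  run <- synthesize_bold(d, list(auditory = reg), spec, quiet_noise())
  wp <- 80   # long enough that the response decays inside the window
  tcs <- estimate_condition_timecourses(list(run), d, window_points = wp)
  # forward oracle: the AO sensory event profile convolved with the HRF
  lags <- (0:(wp - 1)) * spec$tr
  kern_grid <- seq(0, wp * spec$tr, by = spec$tr)
  box <- as.numeric(kern_grid < 3 * spec$tr - 1e-9)
  k <- eval_hrf(reg$hrf, kern_grid)
  pred <- (convolve(box, rev(k), type = "open")[seq_along(lags)]) * spec$tr
  expect_lt(max(abs(tcs[["AO"]]$values - pred)), 0.02 * max(pred))
  # regions silent for a condition stay flat at zero
  expect_lt(max(abs(tcs[["VM"]]$values)), 0.02 * max(pred))
  expect_equal(tcs[["AO"]]$n_trials, sum(d$condition == "AO"))
  expect_equal(tcs[["AO"]]$time[2] - tcs[["AO"]]$time[1], spec$tr)
})

test_that("group splits produce one timecourse per subset", {
  set.seed(24)
  spec <- tiny_spec(trials_per_run = 24, run_volumes = 1100)
  d <- det_trials(spec)
  groups <- d$condition
  ao <- which(groups == "AO")
  groups[ao] <- paste0("AO.Q", rep(1:2, length.out = length(ao)))
  tcs <- estimate_condition_timecourses(
    list(synthesize_bold(d, list(MD = region_model("MD", 4)), spec,
                         quiet_noise(0.05))),
    d, window_points = 30, groups = groups)
  expect_true(all(c("AO.Q1", "AO.Q2", "VM") %in% names(tcs)))
  # conditions with no correct trials are absent with a warning
  d2 <- d; d2$correct[d2$condition == "VM"] <- FALSE
  expect_warning(
    tcs2 <- estimate_condition_timecourses(
      list(synthesize_bold(d2, list(MD = region_model("MD", 4)), spec,
                           quiet_noise(0.05))),
      d2, window_points = 30),
    "VM")
  expect_null(tcs2[["VM"]])
})

test_that("trial-wise whole-event betas recover injected amplitudes", {
  set.seed(25)
  tr <- 0.199; n <- 900
  onsets <- seq(20, 800, by = 110) * tr
  amps <- c(1.5, 0.8, 2.2, 0, 1.1, 0.6, 1.9, 1.3)
  h <- hrf_params()
  sig <- Reduce(`+`, lapply(seq_along(onsets), function(i)
    amps[i] * build_event_regressor(onsets[i], h, tr, n)))
  data <- 1000 * (1 + (sig + rnorm(n, 0, 1e-4)) / 100)
  run <- bold_run(cbind(data, data), tr, roi_labels = c("r", "r"))
  trials <- data.frame(run = 1, trial = seq_along(onsets),
                       onset_t1 = onsets,
                       condition = rep(c("AO", "VM"), 4),
                       task1 = rep(c("AO", "VM"), 4), task2 = NA,
                       soa = NA, map1 = rep(1:4, 2), map2 = NA,
                       rt1 = 1, correct = TRUE)
  tb <- estimate_trial_betas(list(run), trials, h)
  expect_equal(nrow(tb$betas), 8)
  expect_lt(max(abs(tb$betas[, 1] - amps)), 0.01)
  # the zero-amplitude trial's beta is near zero
  expect_lt(abs(tb$betas[4, 1]), 0.01)
})

test_that("least-squares-sum equals all-trials-separate least squares on
           non-overlapping designs and wins under overlap", {
  set.seed(26)
  tr <- 0.199; n <- 600; wp <- 12
  onsets <- c(30, 80, 130, 180, 230) * tr   # spacing > window: orthogonal
  trials <- data.frame(run = 1, trial = 1:5, onset_t1 = onsets,
                       condition = "AO", task1 = "AO", task2 = NA,
                       soa = NA, map1 = 1:5, map2 = NA, rt1 = 1,
                       correct = TRUE)
  prof <- rnorm(wp)
  X_all <- do.call(cbind, lapply(onsets, function(o)
    build_fir_basis(o, wp, tr, n)))
  y <- X_all %*% rep(prof, 5) + 50         # shared per-trial profile
  ys <- 100 * y / mean(y)
  run <- bold_run(cbind(ys), tr)
  attr(run, "scaled") <- TRUE
  lss <- estimate_trialwise_timecourses_lss(list(run), trials,
                                            window_points = wp)
  # all-trials-separate oracle with the same fixed columns
  drift <- cbind(1, serialq:::legendre_basis(n, 3))
  ls_all <- qr.coef(qr(cbind(X_all, drift)), ys)
  for (i in 1:5)
    expect_equal(drop(lss[["AO"]]$betas[, 1, i]),
                 ls_all[(i - 1) * wp + 1:wp],
                 tolerance = 1e-8, ignore_attr = TRUE)
  # distinct per-trial profiles on the same spacing stay within a small
  # coupling tolerance of the LS-all estimate
  prof5 <- matrix(rnorm(wp * 5), wp)
  y5 <- X_all %*% as.vector(prof5) + 50
  y5s <- 100 * y5 / mean(y5)
  run5 <- bold_run(cbind(y5s), tr); attr(run5, "scaled") <- TRUE
  l5 <- estimate_trialwise_timecourses_lss(list(run5), trials,
                                           window_points = wp)
  ls5 <- qr.coef(qr(cbind(X_all, drift)), y5s)
  for (i in 1:5)
    expect_equal(drop(l5[["AO"]]$betas[, 1, i]),
                 ls5[(i - 1) * wp + 1:wp],
                 tolerance = 0.1, ignore_attr = TRUE)
  # overlapping trials: per-trial indicator sets share columns, so the
  # all-trials-separate system is rank deficient (the reason the pooled
  # least-squares-sum model exists); LSS keeps every trial identifiable
  # and stays within a modest factor of the minimum-norm oracle that
  # exploits the (unknowable in practice) shared truth
  skip_if_not_installed("MASS")
  on2 <- c(30, 38, 47, 55, 64) * tr
  X2 <- do.call(cbind, lapply(on2, function(o)
    build_fir_basis(o, wp, tr, n)))
  expect_lt(qr(X2)$rank, ncol(X2))
  tri2 <- trials; tri2$onset_t1 <- on2
  err_lss <- err_all <- NULL
  truth <- rep(prof, 5)
  pinv <- MASS::ginv(cbind(X2, 1))
  for (rep in 1:8) {
    y2 <- drop(X2 %*% truth) + rnorm(n, 0, 1)
    run2 <- bold_run(cbind(y2 + 100), tr); attr(run2, "scaled") <- TRUE
    l2 <- estimate_trialwise_timecourses_lss(list(run2), tri2,
                                             window_points = wp)
    b_lss <- as.vector(sapply(1:5, function(i) l2[["AO"]]$betas[, 1, i]))
    b_all <- drop(pinv %*% y2)[seq_len(5 * wp)]
    err_lss <- c(err_lss, mean((b_lss - truth)^2))
    err_all <- c(err_all, mean((b_all - truth)^2))
  }
  expect_true(all(is.finite(err_lss)))
  expect_lt(mean(err_lss), 1.5 * mean(err_all))
})

test_that("single-trial conditions fall back to plain FIR with a warning", {
  tr <- 0.199
  run <- bold_run(cbind(rnorm(300) + 100), tr)
  attr(run, "scaled") <- TRUE
  trials <- data.frame(run = 1, trial = 1, onset_t1 = 10 * tr,
                       condition = "AO", task1 = "AO", task2 = NA,
                       soa = NA, map1 = 1, map2 = NA, rt1 = 1,
                       correct = TRUE)
  expect_warning(
    l <- estimate_trialwise_timecourses_lss(list(run), trials,
                                            window_points = 8),
    "single correct trial")
  expect_equal(dim(l[["AO"]]$betas), c(8, 1, 1))
})
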