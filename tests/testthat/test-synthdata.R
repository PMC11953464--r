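test_that("region event rules time the neural boxcars correctly", {
  set.seed(12)
  d <- det_trials()   # P=0.3, C=0.6, M=0.15 deterministic
  md <- region_model("MD", 10)
  ev <- simulate_neural_events(d, md)
  # single trials: exactly one central boxcar of duration C
  singles <- d[is.na(d$task2), ]
  for (i in seq_len(nrow(singles))) {
    e <- ev[ev$trial == singles$trial[i], ]
    expect_equal(nrow(e), 1)
    expect_equal(e$duration, 0.6)
    expect_equal(e$onset, singles$onset_t1[i] + 0.3)
  }
  # serial queuing at short SOA: C2 begins at P1+C1 after first onset
  short <- d[!is.na(d$soa) & d$soa == 0.3, ]
  e2 <- ev[ev$trial == short$trial[1], ]
  expect_equal(nrow(e2), 2)
  expect_equal(sort(e2$onset - short$onset_t1[1]), c(0.3, 0.9))
  # long SOA: no postponement, C2 begins at soa + P2
  long <- d[!is.na(d$soa) & d$soa == 1.5, ]
  e3 <- ev[ev$trial == long$trial[1], ]
  expect_equal(sort(e3$onset - long$onset_t1[1]), c(0.3, 1.8))
})

test_that("the parallel model lets central boxcars overlap", {
  set.seed(13)
  dp <- det_trials(model = det_stage_model(serial = FALSE))
  ev <- simulate_neural_events(dp, region_model("MD", 5))
  short <- dp[!is.na(dp$soa) & dp$soa == 0.3, ][1, ]
  e <- ev[ev$trial == short$trial, ]
  on <- sort(e$onset - short$onset_t1)
  expect_equal(on, c(0.3, 0.6))            # C2 at soa + P2, inside C1
  expect_lt(on[2], on[1] + e$duration[1])  # overlap
})

test_that("sensory, motor, execution and suppression rules behave as
           specified", {
  set.seed(14)
  d <- det_trials()
  aud <- simulate_neural_events(d, region_model("auditory", 5,
                                                sensory_dur = 0.5))
  ao_single <- d[d$condition == "AO", ][1, ]
  e <- aud[aud$trial == ao_single$trial, ]
  expect_equal(e$onset, ao_single$onset_t1)       # stimulus-locked
  expect_equal(e$duration, 0.5)
  # auditory region ignores pure VM trials
  vm_single <- d[d$condition == "VM", ][1, ]
  expect_equal(nrow(aud[aud$trial == vm_single$trial, ]), 0)
  # manual motor: spans selection+execution of VM; AO suppresses it
  m1 <- simulate_neural_events(d, region_model("M1", 5, suppression = 0.3))
  em <- m1[m1$trial == vm_single$trial, ]
  expect_equal(em$onset, vm_single$onset_t1 + 0.3)
  expect_equal(em$duration, 0.6 + 0.15)
  es <- m1[m1$trial == ao_single$trial, ]
  expect_equal(es$amplitude, -0.3)
  # execution-locked family: fixed-duration boxcar at the motor stage
  ex <- simulate_neural_events(d, region_model("exec", 5))
  ee <- ex[ex$trial == ao_single$trial, ]
  expect_equal(ee$onset, ao_single$onset_t1 + 0.9)
  expect_equal(ee$duration, 0.15)
  expect_error(region_model("cerebellum"))
})

test_that("zero-noise impulse events reproduce the sampled HRF", {
  set.seed(15)
  spec <- tiny_spec(trials_per_run = 6, run_volumes = 600)
  # one isolated single-task trial: the voxel timecourse must equal the
  # sampled HRF up to the TR integration factor
  d <- data.frame(run = 1, trial = 1L, onset_t1 = 50 * spec$tr,
                  condition = "AO", task1 = "AO", task2 = NA, soa = NA,
                  map1 = 1L, map2 = NA)
  d <- simulate_behavior(d, det_stage_model(), c_scale = 1)
  reg <- region_model("auditory", 3, pattern_gain = 0,
                      sensory_dur = spec$tr)
  run <- synthesize_bold(d, reg = list(auditory = reg), spec,
                         quiet_noise())
  sig <- attr(run, "signal")
  lags <- 0:120
  expected <- eval_hrf(reg$hrf, lags * spec$tr) * spec$tr
  window <- sig[50 + 1 + lags, 1]
  expect_lt(max(abs(window - expected)), 1e-9)
})

test_that("synthesis is seed-reproducible and AR(1) noise is calibrated", {
  spec <- tiny_spec(trials_per_run = 6, run_volumes = 2000)
  d <- det_trials(spec)
  regions <- list(MD = region_model("MD", 4))
  set.seed(77); r1 <- synthesize_bold(d, regions, spec, noise_config())
  set.seed(77); r2 <- synthesize_bold(d, regions, spec, noise_config())
  expect_identical(r1$data, r2$data)
  set.seed(78)
  nr <- synthesize_bold(d[0, ], list(MD = region_model("MD", 6)), spec,
                        noise_config(sigma = 1, phi = 0.5, drift_sd = 0,
                                     n_nuisance = 0))
  ac <- apply(nr$data, 2, function(x)
    acf(x - mean(x), plot = FALSE)$acf[2])
  expect_lt(abs(mean(ac) - 0.5), 0.06)
})

test_that("events and runs round-trip through TSV and NIfTI", {
  set.seed(16)
  spec <- tiny_spec(trials_per_run = 6, run_volumes = 400)
  d <- simulate_behavior(make_design(spec), stage_model(), c_scale = 1)
  f <- tempfile(fileext = ".tsv")
  write_events_tsv(d, f)
  back <- read_events_tsv(f)
  expect_equal(back$onset, d$onset_t1)
  expect_equal(back$trial_type, d$condition)
  expect_equal(back$rt1, d$rt1)
  run <- synthesize_bold(d, list(MD = region_model("MD", 4)), spec,
                         noise_config())
  nf <- tempfile(fileext = ".nii.gz")
  write_bold_nifti(run, nf)
  rb <- read_bold_nifti(nf)
  expect_equal(rb$data, unclass(run$data), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(rb$tr, run$tr)
  expect_equal(rb$roi_labels, run$roi_labels)
  unlink(c(f, nf, sub("\\.nii\\.gz$", ".json", nf)))
})
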