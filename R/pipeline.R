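# End-to-end orchestration: simulate -> estimate -> decode -> latency ->
# quartiles -> Granger causality, from a single nested configuration.

#' Default pipeline configuration
#'
#' Nested configuration for \code{\link{run_pipeline}}. The demo scale
#' (one subject, three study-timed runs) exercises every stage in well
#' under a minute; pass a full \code{\link{design_spec}} block for
#' study-scale sessions.
#'
#' @param seed integer seed governing all randomness.
#' @param ... named blocks overriding the defaults (\code{design},
#'   \code{stage}, \code{noise}, \code{regions}, \code{glm},
#'   \code{decode}, \code{latency}, \code{granger}).
#' @return Nested list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    design = list(n_runs = 3, trials_per_run = 48, run_volumes = 1600),
    stage = list(serial = TRUE),
    noise = list(),
    regions = list(n_voxels = 40, pattern_gain = 1,
                   rois = c("auditory", "MD", "M1", "FEF")),
    glm = list(window_points = 69, drift_order = 3),
    decode = list(k = 30, penalty = 25),
    latency = list(onset_frac = 0.1, shift_mode = "fitted"),
    granger = list(p_max = 5, rois = c("auditory", "MD", "FEF")))
  dots <- list(...)
  for (nm in names(dots))
    cfg[[nm]] <- utils::modifyList(cfg[[nm]], as.list(dots[[nm]]))
  class(cfg) <- "pipeline_config"
  cfg
}

config_objects <- function(cfg) {
  spec <- do.call(design_spec, cfg$design)
  model <- do.call(stage_model, cfg$stage)
  noise <- do.call(noise_config, cfg$noise)
  rois <- cfg$regions$rois
  rargs <- cfg$regions[setdiff(names(cfg$regions), "rois")]
  regions <- lapply(rois, function(r) {
    a <- c(list(roi = r), rargs)
    if (r == "M1") a$suppression <- 0.3
    do.call(region_model, a)
  })
  names(regions) <- rois
  list(spec = spec, model = model, noise = noise, regions = regions)
}

# ROI-mean condition timecourse from an all-voxel estimate
roi_mean_tc <- function(tc, cols) {
  tc$values <- rowMeans(tc$voxel_betas[, cols, drop = FALSE])
  tc
}

#' Run the full analysis pipeline on synthetic data
#'
#' Simulates one subject under the configured design, then runs every
#' analysis stage: behavioral summary (condition RTs and the refractory
#' effect), ROI condition timecourses with spline-fit latency metrics,
#' single-task pattern decoding per ROI, time-resolved decoding of the
#' short-SOA second task against single-task in the central (MD) region,
#' RT-quartile profiles, and Granger causality over the
#' auditory-MD-oculomotor circuit. Deterministic given the config seed.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param outdir optional directory; when given, the events table,
#'   behavioral summary, timecourses, decoding curves and GC matrices
#'   are written as TSV/JSON with the config hash in a provenance file.
#' @return A results bundle (list) with elements \code{behavior},
#'   \code{timecourses}, \code{latency}, \code{decoding},
#'   \code{time_resolved}, \code{quartile}, \code{granger},
#'   \code{provenance}.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  set.seed(config$seed)
  obj <- config_objects(config)
  stage_tag <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", stage, conditionMessage(e)),
           call. = FALSE))
  }
  sim <- stage_tag("simulate",
                   simulate_subject(obj$spec, obj$regions, obj$model,
                                    obj$noise))
  runs <- ensure_scaled(sim$runs)
  trials <- sim$trials
  wp <- config$glm$window_points
  behavior <- sim$behavior

  tcs <- stage_tag("fit",
    estimate_condition_timecourses(runs, trials, window_points = wp,
                                   drift_order = config$glm$drift_order))
  roi_labels <- runs[[1]]$roi_labels
  latency <- list(); timecourses <- list()
  for (r in names(obj$regions)) {
    cols <- which(roi_labels == r)
    timecourses[[r]] <- lapply(tcs, roi_mean_tc, cols = cols)
    latency[[r]] <- lapply(timecourses[[r]], function(tc) {
      curve <- fit_spline(tc$time, tc$values)
      latency_metrics(curve, onset_frac = config$latency$onset_frac)
    })
  }

  tb <- stage_tag("decode",
                  estimate_trial_betas(runs, trials,
                                       drift_order = config$glm$drift_order))
  decoding <- list()
  for (r in names(obj$regions)) {
    cols <- which(roi_labels == r)
    tm <- roi_tmap(list(betas = tb$betas[, cols, drop = FALSE],
                        trials = tb$trials))
    k <- min(config$decode$k, length(cols))
    mode <- if (ncol(tm) > 1) "conjunction" else "single"
    fi <- cols[select_features(tm, k, mode)]
    per_task <- list()
    for (task in c("AO", "VM")) {
      idx <- which(tb$trials$task1 == task)
      per_task[[task]] <- cv_decode(tb$betas[idx, fi, drop = FALSE],
                                    tb$trials$map1[idx],
                                    tb$trials$run[idx],
                                    penalty = config$decode$penalty)$accuracy
    }
    decoding[[r]] <- per_task
  }

  md_cols <- which(roi_labels == "MD")
  tm_md <- roi_tmap(list(betas = tb$betas[, md_cols, drop = FALSE],
                         trials = tb$trials))
  fi_md <- md_cols[select_features(tm_md, min(config$decode$k,
                                              length(md_cols)),
                                   "conjunction")]
  lss <- stage_tag("decode",
    estimate_trialwise_timecourses_lss(
      runs, trials, window_points = wp,
      target_conditions = c("AO", "VM", "S-AOVM", "S-VMAO"),
      drift_order = config$glm$drift_order))
  tr0 <- runs[[1]]$tr
  single_tc <- pool_task_order(
    time_resolved_decode(tb, lss[["AO"]], "AO", fi_md,
                         config$decode$penalty),
    time_resolved_decode(tb, lss[["VM"]], "VM", fi_md,
                         config$decode$penalty))
  t2_tc <- pool_task_order(
    shift_timecourse(time_resolved_decode(tb, lss[["S-VMAO"]], "AO", fi_md,
                                          config$decode$penalty),
                     obj$spec$soa_short, tr0, config$latency$shift_mode),
    shift_timecourse(time_resolved_decode(tb, lss[["S-AOVM"]], "VM", fi_md,
                                          config$decode$penalty),
                     obj$spec$soa_short, tr0, config$latency$shift_mode))
  time_resolved <- list(
    single = single_tc, t2_short = t2_tc,
    single_latency = decode_latency(single_tc),
    t2_latency = decode_latency(t2_tc))

  quartile <- stage_tag("quartile",
    lapply(c(AO = "AO", VM = "VM"), function(cc)
      tryCatch(quartile_profile(runs, trials, cc, roi = "MD",
                                window_points = wp),
               error = function(e) NULL)))

  granger <- stage_tag("granger", {
    g_rois <- intersect(config$granger$rois, names(obj$regions))
    seg_for <- function(cond) {
      l <- lss[[cond]]
      lapply(seq_len(dim(l$betas)[3]), function(i) {
        M <- sapply(g_rois, function(r)
          rowMeans(l$betas[, which(roi_labels == r), i, drop = FALSE]))
        colnames(M) <- g_rois
        M
      })
    }
    seg_ao <- seg_for("AO"); seg_vm <- seg_for("VM")
    p <- select_var_order(seg_ao, config$granger$p_max)
    list(order = p,
         AO = pairwise_conditional_gc(seg_ao, p),
         VM = pairwise_conditional_gc(seg_vm, p))
  })

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  provenance <- list(config_hash = unname(tools::md5sum(tmp)),
                     seed = config$seed,
                     r_version = as.character(getRversion()))
  unlink(tmp)

  bundle <- list(behavior = behavior, timecourses = timecourses,
                 latency = latency, decoding = decoding,
                 time_resolved = time_resolved, quartile = quartile,
                 granger = granger, provenance = provenance)
  if (!is.null(outdir)) write_bundle(bundle, trials, config, outdir)
  bundle
}

write_bundle <- function(bundle, trials, config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_events_tsv(trials, file.path(outdir, "events.tsv"))
  utils::write.table(bundle$behavior$by_condition,
                     file.path(outdir, "behavior.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tc_rows <- NULL
  for (r in names(bundle$timecourses))
    for (cc in names(bundle$timecourses[[r]])) {
      tc <- bundle$timecourses[[r]][[cc]]
      tc_rows <- rbind(tc_rows, data.frame(
        roi = r, condition = cc, time = tc$time, value = tc$values))
    }
  utils::write.table(tc_rows, file.path(outdir, "timecourses.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dec <- data.frame(
    time = bundle$time_resolved$single$time,
    single = bundle$time_resolved$single$accuracy)
  utils::write.table(dec, file.path(outdir, "decoding_single.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(provenance = bundle$provenance,
         prp_s = bundle$behavior$prp,
         granger_AO = bundle$granger$AO$F,
         granger_VM = bundle$granger$VM$F),
    file.path(outdir, "summary.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(outdir)
}

#' Serial-queuing recovery experiment
#'
#' The computational core of the dual-task analysis: simulate subjects
#' whose second-task central stage is (serial model) or is not (parallel
#' model) postponed behind the first task's, run the full
#' estimate-decode-latency pipeline in the central (MD) region, and
#' compare the recovered second-task decoding latency shift against the
#' injected postponement and each subject's behavioral refractory effect.
#'
#' @param n_subjects number of synthetic subjects.
#' @param serial TRUE for the bottleneck model, FALSE for parallel
#'   central processing.
#' @param spec a \code{\link{design_spec}} (default: two runs at study
#'   timing).
#' @param n_voxels MD voxels simulated.
#' @param k features selected (conjunction mode).
#' @param penalty classifier L2 strength.
#' @param noise a \code{\link{noise_config}}.
#' @param window_points FIR window.
#' @param stratified draw the subject central-stage scales as permuted
#'   lognormal quantiles (default), so the realized between-subject mean
#'   matches the population value and recovery error is not confounded
#'   with subject-sampling noise; FALSE for fully random subjects.
#' @return List of class \code{"serial_queue_result"}: \code{subjects}
#'   (data.frame, one row per subject: injected mean central postponement
#'   and PRP, recovered single/T2 peak and onset latencies and their
#'   differences, s), \code{group} (latency metrics of the gamma fits to
#'   the group-mean single and T2 accuracy curves and their differences
#'   — the group-level recovery estimate), and the group-mean curves.
#' @export
serial_queue_experiment <- function(n_subjects = 12, serial = TRUE,
                                    spec = design_spec(n_runs = 4),
                                    n_voxels = 60, k = 50, penalty = 25,
                                    noise = noise_config(),
                                    window_points = 69,
                                    stratified = TRUE) {
  model <- stage_model(serial = serial)
  regions <- list(MD = region_model("MD", n_voxels))
  scales <- if (stratified) {
    q <- stats::qlnorm((seq_len(n_subjects) - 0.5) / n_subjects,
                       -model$subject_sd^2 / 2, model$subject_sd)
    sample(q)
  } else rep(list(NULL), n_subjects)
  out <- NULL
  acc_single <- NULL; acc_t2 <- NULL
  time_single <- NULL; time_t2 <- NULL
  for (s in seq_len(n_subjects)) {
    sim <- simulate_subject(spec, regions, model, noise,
                            c_scale = if (stratified) scales[[s]] else NULL)
    runs <- ensure_scaled(sim$runs)
    trials <- sim$trials
    tb <- estimate_trial_betas(runs, trials)
    fi <- select_features(roi_tmap(tb), min(k, n_voxels), "conjunction")
    lss <- estimate_trialwise_timecourses_lss(
      runs, trials, window_points = window_points,
      target_conditions = c("AO", "VM", "S-AOVM", "S-VMAO"))
    tr0 <- runs[[1]]$tr
    single_tc <- pool_task_order(
      time_resolved_decode(tb, lss[["AO"]], "AO", fi, penalty),
      time_resolved_decode(tb, lss[["VM"]], "VM", fi, penalty))
    t2_tc <- pool_task_order(
      shift_timecourse(time_resolved_decode(tb, lss[["S-VMAO"]], "AO",
                                            fi, penalty),
                       spec$soa_short, tr0, "fitted"),
      shift_timecourse(time_resolved_decode(tb, lss[["S-AOVM"]], "VM",
                                            fi, penalty),
                       spec$soa_short, tr0, "fitted"))
    lat_s <- decode_latency(single_tc)
    lat_t2 <- decode_latency(t2_tc)
    # amplitude-normalize each subject's curves (by their own fitted
    # gains) before group averaging: otherwise slower-central-stage
    # subjects contribute both larger postponements and larger accuracy
    # bumps, weighting the group curve toward late shifts
    norm_acc <- function(tc, lat) {
      A <- lat$curve$params$A
      if (!is.finite(A) || A <= 0.01)
        A <- max(tc$accuracy - 1 / 8, 0.01, na.rm = TRUE)
      (tc$accuracy - 1 / 8) / A + 1 / 8
    }
    acc_single <- cbind(acc_single, norm_acc(single_tc, lat_s))
    acc_t2 <- cbind(acc_t2, norm_acc(t2_tc, lat_t2))
    time_single <- single_tc$time; time_t2 <- t2_tc$time
    short <- !is.na(trials$soa) & trials$soa == spec$soa_short &
      trials$correct
    out <- rbind(out, data.frame(
      subject = s,
      injected_postponement = mean(trials$c2_postponement[short]),
      injected_prp = sim$behavior$prp,
      c_scale = sim$c_scale,
      single_peak = lat_s$peak_s, single_onset = lat_s$onset_s,
      t2_peak = lat_t2$peak_s, t2_onset = lat_t2$onset_s))
  }
  out$peak_shift <- out$t2_peak - out$single_peak
  out$onset_shift <- out$t2_onset - out$single_onset
  g_single <- rowMeans(acc_single, na.rm = TRUE)
  g_t2 <- rowMeans(acc_t2, na.rm = TRUE)
  gl_s <- latency_metrics(fit_single_gamma(time_single, g_single, 1 / 8))
  gl_t <- latency_metrics(fit_single_gamma(time_t2, g_t2, 1 / 8))
  structure(list(
    subjects = out,
    group = list(single = gl_s, t2 = gl_t,
                 peak_shift = gl_t$peak_s - gl_s$peak_s,
                 onset_shift = gl_t$onset_s - gl_s$onset_s,
                 injected = mean(out$injected_postponement)),
    curves = list(time_single = time_single, time_t2 = time_t2,
                  single = g_single, t2 = g_t2)),
    class = "serial_queue_result")
}

#' Quartile-profile discrimination experiment
#'
#' Simulates subjects carrying one duration-scaling (response-selection)
#' region and one pure-shift (execution-locked) region, runs the
#' RT-quartile analysis on both single-task conditions (pooled per
#' region) in a single deconvolution model, and classifies each region's
#' profile with \code{\link{classify_quartile_profile}}. Reports the
#' per-subject metrics and the classification hit rate.
#'
#' @param n_subjects number of synthetic subjects.
#' @param conditions single-task conditions quartiled and pooled.
#' @param spec a \code{\link{design_spec}} (default: four runs at study
#'   timing).
#' @param n_voxels voxels per region.
#' @param noise a \code{\link{noise_config}}.
#' @param window_points FIR window.
#' @return List: \code{metrics} (long data.frame: subject, roi,
#'   condition, quartile metrics), \code{classification} (per subject x
#'   roi: truth, call, evidence), \code{hit_rate} (proportion of
#'   profiles classified correctly).
#' @export
quartile_experiment <- function(n_subjects = 100,
                                conditions = c("AO", "VM"),
                                spec = design_spec(n_runs = 4),
                                n_voxels = 24, noise = noise_config(),
                                window_points = 69) {
  regions <- list(MD = region_model("MD", n_voxels),
                  exec = region_model("exec", n_voxels, amplitude = 4))
  truth <- c(MD = "selection", exec = "execution")
  metrics <- NULL; calls <- NULL
  for (s in seq_len(n_subjects)) {
    sim <- simulate_subject(spec, regions, stage_model(), noise)
    runs <- ensure_scaled(sim$runs)
    trials <- sim$trials
    groups <- trials$condition
    rt_q <- list()
    for (cc in conditions) {
      sel <- trials$condition == cc & trials$correct
      q <- integer(nrow(trials))
      q[sel] <- bin_rt_quartiles(trials$rt1[sel])
      groups[sel] <- paste0(cc, ".Q", q[sel])
      rt_q[[cc]] <- tapply(trials$rt1[sel], q[sel], mean)
    }
    tcs <- suppressWarnings(
      estimate_condition_timecourses(runs, trials,
                                     window_points = window_points,
                                     groups = groups))
    for (r in names(regions)) {
      cols <- which(runs[[1]]$roi_labels == r)
      m <- NULL
      for (cc in conditions) for (kq in 1:4) {
        tc <- roi_mean_tc(tcs[[paste0(cc, ".Q", kq)]], cols)
        mm <- latency_metrics(rebase_curve(fit_spline(tc$time,
                                                      tc$values)))
        m <- rbind(m, data.frame(
          subject = s, roi = r, condition = cc, quartile = kq,
          mean_rt = rt_q[[cc]][[kq]],
          onset_s = mm$onset_s, peak_s = mm$peak_s,
          peak_amplitude = mm$peak_amplitude, fwhm_s = mm$fwhm_s))
      }
      cl <- classify_quartile_profile(m)
      calls <- rbind(calls, data.frame(
        subject = s, roi = r, truth = truth[[r]], call = cl$class,
        rel_amp_slope = cl$rel_amp_slope,
        onset_slope = cl$onset_slope, peak_slope = cl$peak_slope))
      metrics <- rbind(metrics, m)
    }
  }
  list(metrics = metrics, classification = calls,
       hit_rate = mean(calls$call == calls$truth))
}
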