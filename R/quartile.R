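# Quartile-RT analysis: response-selection regions show peak-latency (and
# amplitude/FWHM) increases with slower RT quartiles while onsets hold
# still; pure execution regions shift whole timecourses (onset and peak
# alike) with RT.

#' Rank-based RT quartile labels
#'
#' Splits trials into four near-equal groups by RT rank (counts differ by
#' at most one, extra trials going to the earliest quartiles); ties break
#' by trial order, so a larger RT is never assigned a lower quartile and
#' the labeling is deterministic and invariant to monotone RT shifts.
#'
#' @param rts reaction times (correct trials).
#' @return Integer quartile labels 1..4. When all RTs are identical the
#'   split is by trial order alone and attribute \code{"degenerate"} is
#'   TRUE.
#' @export
bin_rt_quartiles <- function(rts) {
  n <- length(rts)
  if (n < 4) stop("need at least 4 trials to form quartiles")
  ord <- order(rts, seq_len(n))  # stable: ties by trial order
  base <- n %/% 4
  extra <- n %% 4
  counts <- base + (seq_len(4) <= extra)
  lab <- rep(seq_len(4), counts)
  out <- integer(n)
  out[ord] <- lab
  if (length(unique(rts)) == 1) attr(out, "degenerate") <- TRUE
  out
}

#' Quartile-RT BOLD profile for one ROI and task
#'
#' Bins a single-task condition's correct trials into RT quartiles, fits
#' the four-quartile FIR model (one FIR set per quartile), extracts
#' spline-fit latency metrics per quartile, and returns the per-quartile
#' timecourses, metrics, and mean RTs.
#'
#' @param runs list of \code{\link{bold_run}}s.
#' @param trials trial table.
#' @param condition single-task condition (\code{"AO"} or \code{"VM"}).
#' @param roi ROI label (NULL = all voxels).
#' @param window_points FIR window.
#' @param baseline_window early-lag span (s) whose fitted mean serves as
#'   the latency baseline (counters slow pre-response drift; 0 to use a
#'   zero baseline).
#' @return List of class \code{"quartile_result"}: \code{timecourses}
#'   (per quartile), \code{metrics} (data.frame quartile, mean RT, onset,
#'   peak, amplitude, FWHM), \code{condition}, \code{roi}.
#' @export
quartile_profile <- function(runs, trials, condition, roi = NULL,
                             window_points = 69, baseline_window = 0.8) {
  sel <- trials$condition == condition & trials$correct
  if (sum(sel) < 4) stop("too few correct trials in ", condition)
  q <- integer(nrow(trials))
  q[sel] <- bin_rt_quartiles(trials$rt1[sel])
  groups <- ifelse(sel, paste0(condition, ".Q", q), trials$condition)
  tcs <- estimate_condition_timecourses(runs, trials,
                                        window_points = window_points,
                                        roi = roi, groups = groups)
  out_tc <- list(); metrics <- NULL
  for (k in 1:4) {
    g <- paste0(condition, ".Q", k)
    if (is.null(tcs[[g]])) stop("empty quartile ", k, " after filtering")
    tc <- tcs[[g]]
    curve <- fit_spline(tc$time, tc$values)
    curve <- rebase_curve(curve, baseline_window)
    m <- latency_metrics(curve)
    out_tc[[k]] <- tc
    metrics <- rbind(metrics, data.frame(
      quartile = k, mean_rt = mean(trials$rt1[sel][q[sel] == k]),
      onset_s = m$onset_s, peak_s = m$peak_s,
      peak_amplitude = m$peak_amplitude, fwhm_s = m$fwhm_s))
  }
  structure(list(timecourses = out_tc, metrics = metrics,
                 condition = condition, roi = roi),
            class = "quartile_result")
}

#' Classify a quartile profile as selection-like or execution-like
#'
#' A region whose neural event *duration* scales with RT (response
#' selection) produces responses that grow — in amplitude, integral and
#' peak latency — across RT quartiles, while its onset stays relatively
#' still. A region whose fixed-duration event merely *shifts* with RT
#' (pure execution) translates its whole response without growing it.
#' The growth signature is by far the most reliable discriminator at
#' realistic trial counts, so the decision statistic is the quartile
#' regression slope of peak amplitude normalized by the mean amplitude;
#' onset and peak latency slopes are returned as corroborating evidence.
#'
#' @param qr a \code{\link{quartile_profile}} result or a metrics
#'   data.frame with columns \code{quartile}, \code{peak_amplitude},
#'   \code{onset_s}, \code{peak_s} (several conditions' quartile rows may
#'   be pooled).
#' @param threshold relative amplitude slope (per quartile) above which
#'   the profile is called selection-like. The default 0.08 is the
#'   equal-error decision boundary from pilot forward simulations of the
#'   two region families at the generator's default SNR.
#' @return List: \code{class} (\code{"selection"} or \code{"execution"}),
#'   \code{rel_amp_slope}, \code{onset_slope}, \code{peak_slope} (s per
#'   quartile), \code{onset_shift}, \code{peak_shift} (Q4 minus Q1 means).
#' @export
classify_quartile_profile <- function(qr, threshold = 0.08) {
  m <- if (inherits(qr, "quartile_result")) qr$metrics else qr
  slope <- function(y) unname(stats::coef(stats::lm(y ~ m$quartile))[2])
  rel_amp_slope <- slope(m$peak_amplitude) / mean(m$peak_amplitude)
  onset_slope <- slope(m$onset_s)
  peak_slope <- slope(m$peak_s)
  q_mean <- function(y, k) mean(y[m$quartile == k])
  cls <- if (is.finite(rel_amp_slope) && rel_amp_slope > threshold)
    "selection" else "execution"
  list(class = cls, rel_amp_slope = rel_amp_slope,
       onset_slope = onset_slope, peak_slope = peak_slope,
       onset_shift = q_mean(m$onset_s, 4) - q_mean(m$onset_s, 1),
       peak_shift = q_mean(m$peak_s, 4) - q_mean(m$peak_s, 1))
}

#' Omnibus quartile tests across subjects
#'
#' One-way repeated-measures ANOVA per latency metric over the four
#' quartiles, plus the individual-differences correlation between each
#' subject's Q4-Q1 latency change and Q4-Q1 RT change.
#'
#' @param metrics_by_subject list of per-subject \code{metrics}
#'   data.frames from \code{\link{quartile_profile}}.
#' @return List with \code{anova} (per metric:
#'   \code{\link{rm_anova}} results) and \code{individual} (per metric:
#'   \code{\link{pearson_corr}} of Q4-Q1 metric vs Q4-Q1 RT).
#' @export
quartile_group_stats <- function(metrics_by_subject) {
  metrics <- c("onset_s", "peak_s", "peak_amplitude", "fwhm_s")
  mats <- lapply(metrics, function(mm)
    t(sapply(metrics_by_subject, function(d) d[[mm]][order(d$quartile)])))
  names(mats) <- metrics
  rt_diff <- sapply(metrics_by_subject, function(d)
    d$mean_rt[d$quartile == 4] - d$mean_rt[d$quartile == 1])
  anova <- lapply(mats, function(M)
    if (anyNA(M)) NULL else rm_anova(M))
  individual <- lapply(mats, function(M) {
    dd <- M[, 4] - M[, 1]
    if (anyNA(dd)) return(NULL)
    tryCatch(pearson_corr(rt_diff, dd), error = function(e) NULL)
  })
  list(anova = anova, individual = individual)
}
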