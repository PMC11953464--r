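#' Region model: neural event rule, voxel patterns, HRF
#'
#' Describes how one region of interest translates a trial into neural
#' events and voxel activity. Five built-in ROI families mirror the stages
#' of information processing:
#' \describe{
#'   \item{auditory / visual (sensory)}{stimulus-locked boxcar of fixed
#'     duration at its modality's stimulus onset, carrying that task's
#'     mapping-specific pattern.}
#'   \item{MD (central)}{one boxcar per task spanning that task's central
#'     response-selection stage; under serial queuing the second task's
#'     stage is postponed behind the first's.}
#'   \item{M1 / FEF (motor)}{modality-specific boxcar spanning its task's
#'     selection-plus-execution window (central stage onset through the
#'     response), i.e., co-timed with selection rather than purely
#'     execution-locked.}
#'   \item{exec (hypothetical execution-only)}{fixed-duration boxcar
#'     locked to the motor stage onset (so its whole timecourse shifts
#'     with RT); the contrast class for the quartile-RT diagnostics.}
#' }
#' Mapping-specific voxel patterns are i.i.d. Gaussian weight vectors,
#' unit-normalized and fixed per region; each event drives voxel v with
#' amplitude \code{amplitude * (1 + pattern_gain * W[mapping, v])}. The
#' manual motor region optionally receives a negative-amplitude
#' (suppression) boxcar during trials of the non-preferred task.
#'
#' @param roi one of \code{"auditory"}, \code{"visual"}, \code{"MD"},
#'   \code{"M1"}, \code{"FEF"}.
#' @param n_voxels voxels in the region.
#' @param amplitude neural event amplitude (arbitrary units; 1 maps to
#'   roughly 1\% peak signal change for a 1 s event).
#' @param pattern_gain strength of the mapping-specific pattern relative to
#'   the common response.
#' @param suppression amplitude of the negative boxcar for the
#'   non-preferred task (motor regions; 0 disables).
#' @param sensory_dur fixed duration of the stimulus-locked sensory event
#'   (s).
#' @param hrf an \code{\link{hrf_params}} used generatively for this
#'   region.
#' @param n_mappings mappings per task.
#' @return An object of class \code{"region_model"} with a fixed
#'   \code{patterns} list (one mappings-by-voxels matrix per task).
#' @export
region_model <- function(roi, n_voxels = 120, amplitude = 1,
                         pattern_gain = 2, suppression = 0,
                         sensory_dur = 0.5, hrf = hrf_params(),
                         n_mappings = 8) {
  roi <- match.arg(roi, c("auditory", "visual", "MD", "M1", "FEF", "exec"))
  tasks <- switch(roi,
                  auditory = "AO", visual = "VM", MD = c("AO", "VM"),
                  M1 = "VM", FEF = "AO", exec = c("AO", "VM"))
  patterns <- lapply(tasks, function(task) {
    w <- matrix(stats::rnorm(n_mappings * n_voxels), n_mappings, n_voxels)
    w / sqrt(rowSums(w^2))
  })
  names(patterns) <- tasks
  structure(list(roi = roi, n_voxels = n_voxels, amplitude = amplitude,
                 pattern_gain = pattern_gain, suppression = suppression,
                 sensory_dur = sensory_dur, hrf = hrf, tasks = tasks,
                 patterns = patterns, n_mappings = n_mappings),
            class = "region_model")
}

#' Default region set
#'
#' @param n_voxels voxels per region.
#' @param ... passed to \code{\link{region_model}}.
#' @return Named list of \code{region_model}s for the five ROI families;
#'   the manual motor region carries a 0.3-amplitude suppression during
#'   the oculomotor task.
#' @export
default_regions <- function(n_voxels = 120, ...) {
  list(auditory = region_model("auditory", n_voxels, ...),
       visual = region_model("visual", n_voxels, ...),
       MD = region_model("MD", n_voxels, ...),
       M1 = region_model("M1", n_voxels, suppression = 0.3, ...),
       FEF = region_model("FEF", n_voxels, ...))
}

# per-trial task timing from ground-truth stages (absolute run time, s)
trial_task_timing <- function(tr_row) {
  t1 <- tr_row$onset_t1
  out <- list(list(task = tr_row$task1, stim = t1,
                   p = tr_row$p1_dur, c_dur = tr_row$c1_dur,
                   m = tr_row$m1_dur,
                   c_start = t1 + tr_row$p1_dur,
                   mapping = tr_row$map1))
  if (!is.na(tr_row$task2)) {
    t2 <- t1 + tr_row$soa
    c2_start <- t2 + tr_row$p2_dur + tr_row$c2_postponement
    out[[2]] <- list(task = tr_row$task2, stim = t2,
                     p = tr_row$p2_dur, c_dur = tr_row$c2_dur,
                     m = tr_row$m2_dur, c_start = c2_start,
                     mapping = tr_row$map2)
  }
  out
}

#' Per-trial neural event boxcars for a region
#'
#' Applies the region's event rule to every trial of one run's trial
#' table (ground-truth stage durations must be present, i.e., after
#' \code{\link{simulate_behavior}}).
#'
#' @param trials trial table rows for one run.
#' @param region a \code{\link{region_model}}.
#' @return data.frame of events: \code{trial}, \code{task}, \code{mapping},
#'   \code{onset} (s, absolute), \code{duration} (s), \code{amplitude}.
#'   Suppression events carry \code{mapping = NA} and negative amplitude.
#' @export
simulate_neural_events <- function(trials, region) {
  stopifnot(inherits(region, "region_model"))
  if (is.null(trials$c1_dur))
    stop("ground-truth stage durations missing; run simulate_behavior first")
  ev <- list()
  for (i in seq_len(nrow(trials))) {
    row <- trials[i, ]
    for (tk in trial_task_timing(row)) {
      if (tk$task %in% region$tasks) {
        e <- switch(region$roi,
          auditory = ,
          visual = list(onset = tk$stim, duration = region$sensory_dur),
          MD = list(onset = tk$c_start, duration = tk$c_dur),
          M1 = ,
          FEF = list(onset = tk$c_start, duration = tk$c_dur + tk$m),
          exec = list(onset = tk$c_start + tk$c_dur, duration = tk$m))
        ev[[length(ev) + 1]] <- data.frame(
          trial = row$trial, task = tk$task, mapping = tk$mapping,
          onset = e$onset, duration = e$duration,
          amplitude = region$amplitude)
      } else if (region$suppression > 0 && region$roi %in% c("M1", "FEF")) {
        # non-preferred task suppresses the motor region over its
        # selection+execution window
        ev[[length(ev) + 1]] <- data.frame(
          trial = row$trial, task = tk$task, mapping = NA_integer_,
          onset = tk$c_start, duration = tk$c_dur + tk$m,
          amplitude = -region$suppression)
      }
    }
  }
  if (!length(ev))
    return(data.frame(trial = integer(), task = character(),
                      mapping = integer(), onset = numeric(),
                      duration = numeric(), amplitude = numeric()))
  out <- do.call(rbind, ev)
  rownames(out) <- NULL
  out
}
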