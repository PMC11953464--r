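#' Experimental design specification
#'
#' Parameters of one scanning session of the dual-task paradigm: two
#' single-task conditions (AO: auditory-oculomotor; VM: visual-manual) and
#' four dual-task conditions crossing task order with a short or long
#' stimulus-onset asynchrony. Defaults reproduce the study protocol:
#' TR 199 ms, 1600 volumes (318.4 s) per run, 10 runs of 48 trials
#' (8 per condition), SOAs of 300/1500 ms, inter-trial intervals jittered
#' between 3.98 and 11.144 s with mean 5.4 s, 7.96 s pre-run and 9.96 s
#' post-run rest, and 8 stimulus-response mappings per task.
#'
#' The inter-trial interval runs from second-task stimulus offset (stimulus
#' duration 0.2 s) to the next trial's first stimulus onset; with that
#' definition the default design fits the 318.4 s run.
#'
#' @param tr repetition time (s).
#' @param run_volumes volumes per run.
#' @param n_runs runs per session.
#' @param trials_per_run trials per run (multiple of the number of
#'   conditions).
#' @param soa_short,soa_long stimulus-onset asynchronies (s).
#' @param iti_min,iti_max,iti_mean inter-trial interval bounds and target
#'   mean (s).
#' @param rest_pre,rest_post rest periods before the first and after the
#'   last trial (s).
#' @param stim_dur stimulus duration (s).
#' @param n_mappings stimulus-response mappings per task.
#' @return An object of class \code{"design_spec"}.
#' @export
design_spec <- function(tr = 0.199, run_volumes = 1600, n_runs = 10,
                        trials_per_run = 48, soa_short = 0.3, soa_long = 1.5,
                        iti_min = 3.98, iti_max = 11.144, iti_mean = 5.4,
                        rest_pre = 7.96, rest_post = 9.96, stim_dur = 0.2,
                        n_mappings = 8) {
  stopifnot(tr > 0, run_volumes > 0, n_runs >= 1, trials_per_run >= 6)
  if (trials_per_run %% 6 != 0)
    stop("'trials_per_run' must be a multiple of the 6 conditions")
  if (!(iti_min <= iti_mean && iti_mean <= iti_max))
    stop("'iti_mean' must lie within [iti_min, iti_max]")
  structure(list(tr = tr, run_volumes = run_volumes, n_runs = n_runs,
                 trials_per_run = trials_per_run,
                 conditions = c("AO", "VM", "S-AOVM", "L-AOVM",
                                "S-VMAO", "L-VMAO"),
                 soa_short = soa_short, soa_long = soa_long,
                 iti_min = iti_min, iti_max = iti_max, iti_mean = iti_mean,
                 rest_pre = rest_pre, rest_post = rest_post,
                 stim_dur = stim_dur, n_mappings = n_mappings),
            class = "design_spec")
}

run_duration <- function(spec) spec$run_volumes * spec$tr

# condition -> (task1, task2, soa); single tasks have no task2/soa
condition_table <- function(spec) {
  data.frame(
    condition = spec$conditions,
    task1 = c("AO", "VM", "AO", "AO", "VM", "VM"),
    task2 = c(NA, NA, "VM", "VM", "AO", "AO"),
    soa = c(NA, NA, spec$soa_short, spec$soa_long,
            spec$soa_short, spec$soa_long),
    stringsAsFactors = FALSE)
}

# Truncated decaying-exponential ITI law on the TR grid. The support is the
# set of TR multiples in [iti_min, iti_max]; the rate is solved numerically
# so the theoretical mean equals iti_mean.
iti_law <- function(spec) {
  kmin <- ceiling(spec$iti_min / spec$tr - 1e-9)
  kmax <- floor(spec$iti_max / spec$tr + 1e-9)
  x <- (kmin:kmax) * spec$tr
  mean_at <- function(rate) {
    w <- exp(-rate * (x - x[1]))   # shift for numerical stability
    sum(x * w) / sum(w)
  }
  if (!(spec$iti_mean > min(x) && spec$iti_mean < mean_at(0)))
    stop(sprintf(
      "ITI calibration failure: mean %.3f s not attainable on [%.3f, %.3f]",
      spec$iti_mean, min(x), mean_at(0)))
  rate <- stats::uniroot(function(r) mean_at(r) - spec$iti_mean,
                         lower = 1e-9, upper = 50, tol = 1e-12)$root
  w <- exp(-rate * (x - x[1]))
  list(values = x, prob = w / sum(w), rate = rate)
}

#' Sample inter-trial intervals
#'
#' Draws ITIs from a truncated decaying-exponential distribution restricted
#' to the TR grid, with the decay rate calibrated so the theoretical mean
#' equals \code{spec$iti_mean} (5.4 s by default, on [3.98, 11.144] s).
#'
#' @param spec a \code{\link{design_spec}}.
#' @param n number of intervals (>= 0).
#' @return Numeric vector of \code{n} durations (s), each an integer
#'   multiple of the TR.
#' @export
sample_itis <- function(spec, n) {
  stopifnot(n >= 0)
  if (n == 0) return(numeric(0))
  law <- iti_law(spec)
  sample(law$values, n, replace = TRUE, prob = law$prob)
}

#' Generate a balanced, randomized trial table
#'
#' Builds a session of trials: per run, equal numbers of the six conditions
#' in random order, with each task's stimulus-response mappings balanced
#' within run when \code{trials_per_run} is a multiple of
#' \code{6 * n_mappings} (and assigned as balanced as possible otherwise).
#' First-stimulus onsets are placed on the TR grid, separated by the trial's
#' occupied window (SOA + stimulus duration) plus a jittered ITI; runs whose
#' sampled ITIs would overflow the run length are re-jittered a bounded
#' number of times before failing.
#'
#' @param spec a \code{\link{design_spec}}.
#' @param max_tries ITI re-jitter attempts per run before a packing error.
#' @return A data.frame with one row per trial: \code{run}, \code{trial}
#'   (within-run index), \code{onset_t1} (s, TR grid), \code{condition},
#'   \code{task1}, \code{task2}, \code{soa}, \code{map1}, \code{map2}.
#'   RT and correctness columns are added by
#'   \code{\link{simulate_behavior}}.
#' @export
make_design <- function(spec, max_tries = 200) {
  stopifnot(inherits(spec, "design_spec"))
  ct <- condition_table(spec)
  per_cond <- spec$trials_per_run / 6
  rows <- vector("list", spec$n_runs)
  for (r in seq_len(spec$n_runs)) {
    cond <- rep(ct$condition, each = per_cond)
    # balanced mapping assignment per task within run
    assign_maps <- function(n) {
      m <- rep_len(seq_len(spec$n_mappings), n)
      sample(m, n)
    }
    df <- data.frame(condition = cond, stringsAsFactors = FALSE)
    idx <- match(df$condition, ct$condition)
    df$task1 <- ct$task1[idx]
    df$task2 <- ct$task2[idx]
    df$soa <- ct$soa[idx]
    # exact (condition x mapping) balance: within each condition's trials,
    # each task's mappings cycle through 1..n_mappings (randomized order);
    # this also balances mappings per task across the whole run
    df$map1 <- NA_integer_; df$map2 <- NA_integer_
    for (cc in unique(df$condition)) {
      ic <- which(df$condition == cc)
      df$map1[ic] <- assign_maps(length(ic))
      if (!is.na(df$task2[ic[1]]))
        df$map2[ic] <- assign_maps(length(ic))
    }
    df <- df[sample(nrow(df)), , drop = FALSE]
    occupied <- ifelse(is.na(df$soa), 0, df$soa) + spec$stim_dur
    n <- nrow(df)
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      itis <- sample_itis(spec, n - 1)
      onset <- numeric(n)
      onset[1] <- round(spec$rest_pre / spec$tr) * spec$tr
      if (n > 1) for (i in 2:n) {
        t_next <- onset[i - 1] + occupied[i - 1] + itis[i - 1]
        onset[i] <- ceiling(t_next / spec$tr - 1e-9) * spec$tr
      }
      if (onset[n] + occupied[n] + spec$rest_post <=
          run_duration(spec) + 1e-9) { ok <- TRUE; break }
    }
    if (!ok)
      stop(sprintf(
        "infeasible packing in run %d: %d trials with the given ITI law %s",
        r, n, "exceed the run length"))
    df$onset_t1 <- onset
    df$run <- r
    df$trial <- seq_len(n)
    rows[[r]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("run", "trial", "onset_t1", "condition", "task1", "task2",
          "soa", "map1", "map2")]
}
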