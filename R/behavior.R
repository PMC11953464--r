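#' Central-bottleneck stage-duration model
#'
#' Reaction times decompose into a perceptual stage P, a central
#' response-selection stage C, and a motor stage M. Stage durations are
#' gamma distributed with configurable means and coefficients of variation;
#' the central stage carries most of the duration and most of the
#' variability, as expected for 8-alternative arbitrary mappings. The
#' defaults are calibrated so that the single-task mean RT is 1.066 s and
#' the mean central postponement at the short (300 ms) SOA equals
#' \code{mean_c - soa_short} = 0.535 s, reproducing the observed group
#' behavior (single 1066 ms; second-task RT 1601 ms at short vs. 1066 ms at
#' long SOA under the serial model).
#'
#' Under the serial (bottleneck) model the second task's central stage
#' cannot begin before the first task's central stage has finished; under
#' the parallel variant both central stages run independently.
#'
#' @param mean_p,mean_c,mean_m stage means (s).
#' @param cv_p,cv_c,cv_m coefficients of variation (gamma shape =
#'   \code{1/cv^2}).
#' @param subject_sd between-subject lognormal scale jitter on the central
#'   stage mean.
#' @param accuracy per-response probability of a correct response.
#' @param serial logical; serial queuing (TRUE) or parallel central
#'   processing (FALSE).
#' @return An object of class \code{"stage_model"}.
#' @export
stage_model <- function(mean_p = 0.100, mean_c = 0.835, mean_m = 0.131,
                        cv_p = 0.1, cv_c = 0.25, cv_m = 0.1,
                        subject_sd = 0.25, accuracy = 0.9, serial = TRUE) {
  stopifnot(mean_p > 0, mean_c > 0, mean_m > 0,
            accuracy >= 0, accuracy <= 1)
  structure(list(mean_p = mean_p, mean_c = mean_c, mean_m = mean_m,
                 cv_p = cv_p, cv_c = cv_c, cv_m = cv_m,
                 subject_sd = subject_sd, accuracy = accuracy,
                 serial = serial),
            class = "stage_model")
}

draw_stage <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

#' Simulate dual-task behavior under the bottleneck model
#'
#' Fills in reaction times, correctness flags and ground-truth stage
#' durations for a trial table. The first response time is
#' \code{P1 + C1 + M1}. Under serial queuing the second task's central
#' stage waits for the first's, so
#' \code{rt2 = max(P2, P1 + C1 - soa) + C2 + M2} (measured from the second
#' stimulus onset); under the parallel model \code{rt2 = P2 + C2 + M2}.
#' A per-subject lognormal multiplier on the central-stage mean produces
#' between-subject differences in both RT and the size of the refractory
#' effect.
#'
#' @param trials a trial table from \code{\link{make_design}}.
#' @param model a \code{\link{stage_model}}.
#' @param c_scale optional fixed multiplier on the central-stage mean
#'   (overrides the random subject jitter; 1 = population mean).
#' @return The trial table with columns \code{rt1}, \code{rt2},
#'   \code{correct1}, \code{correct2}, \code{correct} (all responses
#'   correct), per-task stage durations \code{p1_dur}, \code{c1_dur},
#'   \code{m1_dur}, \code{p2_dur}, \code{c2_dur}, \code{m2_dur}, and
#'   \code{c2_postponement} (delay of the second central stage beyond its
#'   earliest possible start, 0 for singles and under the parallel model).
#'   The realized subject scale is stored in attribute
#'   \code{"c_scale"}.
#' @export
simulate_behavior <- function(trials, model = stage_model(),
                              c_scale = NULL) {
  stopifnot(inherits(model, "stage_model"))
  if (any(!is.na(trials$soa) & trials$soa < 0))
    stop("negative SOA rejected")
  n <- nrow(trials)
  if (is.null(c_scale))
    c_scale <- exp(stats::rnorm(1, 0, model$subject_sd) -
                   model$subject_sd^2 / 2)
  mc <- model$mean_c * c_scale
  trials$p1_dur <- draw_stage(n, model$mean_p, model$cv_p)
  trials$c1_dur <- draw_stage(n, mc, model$cv_c)
  trials$m1_dur <- draw_stage(n, model$mean_m, model$cv_m)
  dual <- !is.na(trials$task2)
  trials$p2_dur <- ifelse(dual, draw_stage(n, model$mean_p, model$cv_p), NA)
  trials$c2_dur <- ifelse(dual, draw_stage(n, mc, model$cv_c), NA)
  trials$m2_dur <- ifelse(dual, draw_stage(n, model$mean_m, model$cv_m), NA)
  trials$rt1 <- trials$p1_dur + trials$c1_dur + trials$m1_dur
  c1_end <- trials$p1_dur + trials$c1_dur          # from T1 onset
  if (model$serial) {
    c2_start <- pmax(trials$p2_dur, c1_end - trials$soa)  # from T2 onset
  } else {
    c2_start <- trials$p2_dur
  }
  trials$c2_postponement <- ifelse(dual, c2_start - trials$p2_dur, 0)
  trials$rt2 <- ifelse(dual, c2_start + trials$c2_dur + trials$m2_dur, NA)
  trials$correct1 <- stats::runif(n) < model$accuracy
  trials$correct2 <- ifelse(dual, stats::runif(n) < model$accuracy, NA)
  trials$correct <- trials$correct1 & (!dual | trials$correct2)
  attr(trials, "c_scale") <- c_scale
  trials
}

#' Behavioral summary: condition means and the refractory effect
#'
#' Mean first- and second-response RTs per condition (correct trials only),
#' task orders pooled, and the psychological refractory period
#' PRP = mean RT2(short SOA) - mean RT2(long SOA), with a paired test
#' across runs when possible.
#'
#' @param trials a trial table with behavior
#'   (\code{\link{simulate_behavior}}).
#' @return A list with \code{by_condition} (data.frame of n, mean rt1/rt2),
#'   \code{single_rt}, \code{rt2_short}, \code{rt2_long} and \code{prp}
#'   (s).
#' @export
summarize_behavior <- function(trials) {
  ok <- trials[which(trials$correct), , drop = FALSE]
  if (!nrow(ok)) stop("no correct trials to summarize")
  agg <- do.call(rbind, lapply(split(ok, ok$condition), function(d)
    data.frame(condition = d$condition[1], n = nrow(d),
               rt1 = mean(d$rt1), rt2 = mean(d$rt2),
               stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  dual <- !is.na(ok$task2)
  short <- dual & ok$soa == min(ok$soa[dual])
  long <- dual & ok$soa == max(ok$soa[dual])
  single <- !dual
  res <- list(
    by_condition = agg,
    single_rt = mean(ok$rt1[single]),
    rt2_short = if (any(short)) mean(ok$rt2[short]) else NA_real_,
    rt2_long = if (any(long)) mean(ok$rt2[long]) else NA_real_)
  res$prp <- res$rt2_short - res$rt2_long
  res
}
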