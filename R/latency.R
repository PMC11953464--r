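#' Fitted-curve container
#'
#' A continuous evaluator over a trial window, with a baseline reference
#' level: 0 for percent-signal timecourses, the chance rate (1/8) for
#' decoding-accuracy timecourses.
#'
#' @param evaluator function of time (s), vectorized.
#' @param window numeric length-2 window \code{c(t0, t1)} on which the
#'   evaluator is defined.
#' @param kind one of \code{"spline"}, \code{"single_gamma"},
#'   \code{"double_gamma"}, \code{"interp"}.
#' @param params kind-specific parameter list.
#' @param baseline constant reference level.
#' @return An object of class \code{"fitted_curve"}.
#' @export
fitted_curve <- function(evaluator, window, kind, params = list(),
                         baseline = 0) {
  stopifnot(is.function(evaluator), length(window) == 2, window[2] > window[1])
  structure(list(evaluator = evaluator, window = window, kind = kind,
                 params = params, baseline = baseline),
            class = "fitted_curve")
}

# set a fitted curve's baseline to its mean over the first span seconds
# (pre-response lags), countering slow baseline wander in deconvolved
# timecourses
rebase_curve <- function(curve, span = 0.8) {
  if (span <= 0) return(curve)
  tt <- seq(curve$window[1], min(curve$window[1] + span, curve$window[2]),
            length.out = 9)
  curve$baseline <- curve$baseline + mean(curve$evaluator(tt))
  curve
}

# linear-interpolation curve through raw samples (used by forward simulations)
fitted_curve_from_samples <- function(time, values, baseline = 0) {
  f <- stats::approxfun(time, values, rule = 2)
  fitted_curve(f, range(time), "interp", baseline = baseline)
}

#' Smoothing-spline fit to a condition timecourse
#'
#' Cubic smoothing spline with the smoothing parameter chosen by generalized
#' cross-validation, the data-driven curve fit used for ROI-mean
#' percent-signal timecourses.
#'
#' @param time sample times (s).
#' @param values sampled response.
#' @param baseline reference level stored with the curve (default 0).
#' @return A \code{\link{fitted_curve}} of kind \code{"spline"}.
#' @export
fit_spline <- function(time, values, baseline = 0) {
  stopifnot(length(time) == length(values))
  ok <- is.finite(values)
  time <- time[ok]; values <- values[ok]
  if (length(time) < 10) stop("need at least 10 points for the spline fit")
  if (stats::sd(values) == 0) {
    v <- values[1]
    return(fitted_curve(function(t) rep(v, length(t)), range(time), "spline",
                        params = list(constant = v), baseline = baseline))
  }
  sp <- stats::smooth.spline(time, values, cv = FALSE)  # GCV
  fitted_curve(function(t) stats::predict(sp, t)$y, range(time), "spline",
               params = list(spar = sp$spar, lambda = sp$lambda, df = sp$df),
               baseline = baseline)
}

#' Single-gamma fit to a (noisy) timecourse
#'
#' Fits \code{baseline + A * g(t; p, f)} where \code{g} is the unit-peak
#' gamma lobe of the double-gamma model, with the baseline held fixed.
#' Used for decoding-accuracy timecourses, which are too noisy for the
#' spline fit; the baseline is the chance rate there.
#'
#' @param time sample times (s).
#' @param values sampled response.
#' @param baseline fixed reference level (e.g., 0.125 for 8-way decoding).
#' @param init optional initial \code{c(A, p, f)}.
#' @return A \code{\link{fitted_curve}} of kind \code{"single_gamma"} whose
#'   \code{params} hold \code{A}, \code{p}, \code{f}.
#' @export
fit_single_gamma <- function(time, values, baseline, init = NULL) {
  stopifnot(length(time) == length(values))
  ok <- is.finite(values)
  time <- time[ok]; values <- values[ok]
  y <- values - baseline
  if (is.null(init)) {
    A0 <- max(y)
    p0 <- time[which.max(y)]
    init <- c(A = max(A0, 1e-3), p = min(max(p0, 1), max(time)), f = 3)
  }
  lower <- c(-10 * max(abs(y), 1e-6), 0.3, 0.3)
  upper <- c(10 * max(abs(y), 1e-6), 2 * max(time), 30)
  obj <- function(th) {
    th <- pmin(pmax(th, lower), upper)
    sum((y - th[1] * gamma_lobe(time, th[2], th[3]))^2)
  }
  fit <- tryCatch(
    stats::optim(init, obj, method = "L-BFGS-B", lower = lower,
                 upper = upper, control = list(maxit = 500, factr = 1e4)),
    error = function(e) NULL)
  if (is.null(fit) || fit$convergence != 0) {
    # line-search failures happen on plateau-like curves; the simplex
    # restart is slower but robust
    fit <- stats::optim(init, obj, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-12))
    if (fit$convergence != 0)
      stop("single-gamma fit did not converge: ", fit$message)
    fit$par <- pmin(pmax(fit$par, lower), upper)
  }
  A <- fit$par[1]; p <- fit$par[2]; f <- fit$par[3]
  fitted_curve(function(t) baseline + A * gamma_lobe(t, p, f),
               c(0, max(time)), "single_gamma",
               params = list(A = A, p = p, f = f, rss = fit$value),
               baseline = baseline)
}

#' Paired single-gamma fit with a shared width
#'
#' Fits \code{baseline + A_i * g(t; p_i, f)} jointly to two timecourses
#' with a common width \code{f}. Untying only the gains and
#' times-to-peak removes the strong p-f-A tradeoff that makes
#' independently fitted peak latencies of broad accuracy curves
#' unstable, so the difference \code{p2 - p1} is a low-variance estimate
#' of the temporal shift between two curves of (near-)common shape.
#'
#' @param time1,values1 first timecourse.
#' @param time2,values2 second timecourse.
#' @param baseline fixed reference level for both curves.
#' @return List with fitted \code{A1}, \code{p1}, \code{A2}, \code{p2},
#'   \code{f}, the implied \code{shift} (\code{p2 - p1}), and both
#'   \code{\link{fitted_curve}} objects.
#' @export
fit_gamma_pair <- function(time1, values1, time2, values2, baseline) {
  ok1 <- is.finite(values1); ok2 <- is.finite(values2)
  f1 <- fit_single_gamma(time1[ok1], values1[ok1], baseline)
  f2 <- fit_single_gamma(time2[ok2], values2[ok2], baseline)
  y1 <- values1[ok1] - baseline; y2 <- values2[ok2] - baseline
  obj <- function(th)
    sum((y1 - th[1] * gamma_lobe(time1[ok1], th[2], th[5]))^2) +
    sum((y2 - th[3] * gamma_lobe(time2[ok2], th[4], th[5]))^2)
  init <- c(f1$params$A, f1$params$p, f2$params$A, f2$params$p,
            mean(c(f1$params$f, f2$params$f)))
  sc <- max(abs(c(y1, y2)), 1e-6)
  fit <- stats::optim(init, obj, method = "L-BFGS-B",
                      lower = c(-10 * sc, 0.3, -10 * sc, 0.3, 0.3),
                      upper = c(10 * sc, 2 * max(time1, time2),
                                10 * sc, 2 * max(time1, time2), 30),
                      control = list(maxit = 1000, factr = 1e4))
  th <- fit$par
  mk <- function(A, p) fitted_curve(
    function(t) baseline + A * gamma_lobe(t, p, th[5]),
    c(0, max(time1, time2)), "single_gamma",
    params = list(A = A, p = p, f = th[5]), baseline = baseline)
  list(A1 = th[1], p1 = th[2], A2 = th[3], p2 = th[4], f = th[5],
       shift = th[4] - th[2], curve1 = mk(th[1], th[2]),
       curve2 = mk(th[3], th[4]))
}

#' Onset latency, peak latency, amplitude and FWHM of a fitted curve
#'
#' Peak latency is the argmax of the curve over a dense grid with parabolic
#' refinement; peak amplitude is measured above the curve's baseline. Onset
#' latency is the earliest ascending crossing of baseline + 10\% of the peak
#' amplitude before the peak (threshold fraction configurable). FWHM is the
#' width between the half-amplitude crossings bracketing the peak; if the
#' curve never falls back to half amplitude inside the window the metric is
#' \code{NA} and flagged.
#'
#' @param curve a \code{\link{fitted_curve}}.
#' @param onset_frac threshold fraction of peak amplitude for the onset
#'   (default 0.1).
#' @param grid_dt search grid resolution (s, default 0.01).
#' @return A list with \code{onset_s}, \code{peak_s}, \code{peak_amplitude},
#'   \code{fwhm_s} and logical \code{defined}.
#' @export
latency_metrics <- function(curve, onset_frac = 0.1, grid_dt = 0.01) {
  stopifnot(inherits(curve, "fitted_curve"))
  tt <- seq(curve$window[1], curve$window[2], by = grid_dt)
  y <- curve$evaluator(tt) - curve$baseline
  i <- which.max(y)
  amp <- y[i]
  if (!is.finite(amp) || amp <= 0)
    return(list(onset_s = NA_real_, peak_s = NA_real_,
                peak_amplitude = NA_real_, fwhm_s = NA_real_,
                defined = FALSE))
  peak <- tt[i]
  if (i > 1 && i < length(tt)) {       # parabolic refinement
    y1 <- y[i - 1]; y2 <- y[i]; y3 <- y[i + 1]
    den <- y1 - 2 * y2 + y3
    if (den < 0) {
      delta <- 0.5 * (y1 - y3) / den
      peak <- tt[i] + delta * grid_dt
      amp <- y2 - 0.25 * (y1 - y3) * delta
    }
  }
  cross_up <- function(th, upto) {
    idx <- which(y[seq_len(upto - 1)] < th & y[2:upto] >= th)
    if (!length(idx)) return(NA_real_)
    j <- idx[1]
    tt[j] + grid_dt * (th - y[j]) / (y[j + 1] - y[j])
  }
  onset <- cross_up(onset_frac * amp, i)
  if (is.na(onset) && y[1] >= onset_frac * amp) onset <- tt[1]
  half <- 0.5 * amp
  left <- cross_up(half, i)
  if (is.na(left) && y[1] >= half) left <- tt[1]
  idx_dn <- which(y[i:(length(y) - 1)] >= half & y[(i + 1):length(y)] < half)
  right <- if (length(idx_dn)) {
    j <- i + idx_dn[1] - 1
    tt[j] + grid_dt * (y[j] - half) / (y[j] - y[j + 1])
  } else NA_real_
  fwhm <- right - left
  list(onset_s = onset, peak_s = peak, peak_amplitude = amp,
       fwhm_s = if (is.na(fwhm)) NA_real_ else fwhm,
       defined = TRUE)
}

#' Temporal shift applied when aligning second-task timecourses
#'
#' Raw (TR-sampled) timecourses can only be shifted by whole numbers of TRs:
#' the applied shift is the largest TR multiple not exceeding the SOA
#' (floor rule), giving 199 ms for a 300 ms SOA and 1393 ms for a 1500 ms
#' SOA at TR = 199 ms. Curve-fitted data are shifted by the exact SOA.
#'
#' @param soa stimulus-onset asynchrony (s), non-negative.
#' @param tr repetition time (s).
#' @param mode \code{"raw"} or \code{"fitted"}.
#' @return The shift in seconds.
#' @export
soa_shift <- function(soa, tr, mode = c("raw", "fitted")) {
  mode <- match.arg(mode)
  stopifnot(soa >= 0, tr > 0)
  if (mode == "fitted") soa else floor(soa / tr) * tr
}

#' Shift a timecourse's time origin for second-task alignment
#'
#' Subtracts the applicable \code{\link{soa_shift}} from the time grid
#' (leftward shift), re-expressing a timecourse measured from first-task
#' onset relative to second-task onset.
#'
#' @param tc a list with fields \code{time} and \code{values} (a
#'   \code{condition_timecourse} or \code{decoding_timecourse}).
#' @param soa SOA (s).
#' @param tr repetition time (s).
#' @param mode \code{"raw"} or \code{"fitted"}.
#' @return The timecourse with shifted \code{time}; the applied shift (s)
#'   is stored in attribute \code{"shift"}.
#' @export
shift_timecourse <- function(tc, soa, tr, mode = c("raw", "fitted")) {
  mode <- match.arg(mode)
  s <- soa_shift(soa, tr, mode)
  tc$time <- tc$time - s
  attr(tc, "shift") <- s
  tc
}
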