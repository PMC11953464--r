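#' Noise configuration for BOLD synthesis
#'
#' Voxel timeseries are generated in percent-signal units as
#' signal + AR(1) noise + slow polynomial drift + shared low-frequency
#' nuisance components, then mapped to arbitrary scanner units around a
#' per-voxel baseline level.
#'
#' @param sigma marginal standard deviation of the AR(1) noise (\% signal).
#' @param phi AR(1) coefficient.
#' @param drift_sd standard deviation of the random Legendre drift
#'   coefficients (\% signal), orders 1..3 per run.
#' @param n_nuisance number of shared sinusoidal nuisance components.
#' @param nuisance_sd per-voxel loading sd on the shared components.
#' @param base_level mean scanner level (arbitrary units).
#' @return A list of class \code{"noise_config"}.
#' @export
noise_config <- function(sigma = 0.3, phi = 0.3, drift_sd = 1,
                         n_nuisance = 2, nuisance_sd = 0.2,
                         base_level = 1000) {
  stopifnot(sigma >= 0, abs(phi) < 1)
  structure(list(sigma = sigma, phi = phi, drift_sd = drift_sd,
                 n_nuisance = n_nuisance, nuisance_sd = nuisance_sd,
                 base_level = base_level),
            class = "noise_config")
}

ar1_noise <- function(n, sigma, phi) {
  if (sigma == 0) return(numeric(n))
  innov <- stats::rnorm(n, 0, sigma * sqrt(1 - phi^2))
  innov[1] <- stats::rnorm(1, 0, sigma)
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

# orthogonal polynomial drift basis on [0, 1], orders 1..order (no constant)
legendre_basis <- function(n, order = 3) {
  x <- seq(-1, 1, length.out = n)
  p <- list(x, (3 * x^2 - 1) / 2, (5 * x^3 - 3 * x) / 2,
            (35 * x^4 - 30 * x^2 + 3) / 8)
  do.call(cbind, p[seq_len(order)])
}

#' BOLD run container
#'
#' @param data time-by-voxel matrix (rows = volumes).
#' @param tr repetition time (s).
#' @param run run id.
#' @param roi_labels per-voxel (column) region label.
#' @param nuisance time-by-k matrix of known nuisance regressors (may have
#'   0 columns).
#' @param censor logical per-volume keep flag.
#' @return Object of class \code{"bold_run"}.
#' @export
bold_run <- function(data, tr, run = 1L,
                     roi_labels = rep("roi", ncol(data)),
                     nuisance = matrix(0, nrow(data), 0),
                     censor = rep(TRUE, nrow(data))) {
  data <- as.matrix(data)
  stopifnot(length(roi_labels) == ncol(data),
            nrow(nuisance) == nrow(data),
            length(censor) == nrow(data),
            !anyNA(data))
  structure(list(data = data, tr = tr, run = run, roi_labels = roi_labels,
                 nuisance = nuisance, censor = censor),
            class = "bold_run")
}

# event boxcar train sampled on the TR grid with fractional bin overlap,
# preserving sub-TR event timing
event_train <- function(onsets, durations, amplitudes, tr, n_volumes) {
  train <- numeric(n_volumes)
  t0 <- (seq_len(n_volumes) - 1) * tr
  for (i in seq_along(onsets)) {
    a <- onsets[i]; b <- onsets[i] + durations[i]
    lo <- max(1L, floor(a / tr) + 1L)
    hi <- min(n_volumes, ceiling(b / tr))
    if (hi < lo) next
    idx <- lo:hi
    ov <- pmax(0, pmin(b, t0[idx] + tr) - pmax(a, t0[idx])) / tr
    train[idx] <- train[idx] + amplitudes[i] * ov
  }
  train
}

#' Synthesize one run of voxelwise BOLD data
#'
#' For each region, per-trial neural boxcars (from the region's event rule
#' and the trial ground truth) drive each voxel with the region's common
#' amplitude modulated by its mapping-specific pattern weight; the voxel
#' event train is convolved with the region's HRF at the TR resolution and
#' AR(1) noise, random polynomial drift and shared nuisance components are
#' added. Deterministic given the RNG state.
#'
#' @param trials trial rows of one run (with ground-truth stages).
#' @param regions named list of \code{\link{region_model}}s.
#' @param spec the \code{\link{design_spec}}.
#' @param noise a \code{\link{noise_config}}.
#' @return A \code{\link{bold_run}} whose columns concatenate the regions
#'   (labels in \code{roi_labels}); attribute \code{"signal"} holds the
#'   noiseless percent-signal matrix.
#' @export
synthesize_bold <- function(trials, regions, spec, noise = noise_config()) {
  nv_total <- sum(vapply(regions, function(r) r$n_voxels, 0))
  nt <- spec$run_volumes
  sig <- matrix(0, nt, nv_total)
  labels <- character(nv_total)
  col0 <- 0L
  for (rn in names(regions)) {
    reg <- regions[[rn]]
    cols <- col0 + seq_len(reg$n_voxels)
    labels[cols] <- rn
    ev <- simulate_neural_events(trials, reg)
    if (nrow(ev)) {
      kern <- hrf_kernel(reg$hrf, spec$tr, duration = 30)
      # group events by (task, mapping) so each group shares one loading
      key <- paste(ev$task, ev$mapping)
      for (k in unique(key)) {
        e <- ev[key == k, , drop = FALSE]
        train <- event_train(e$onset, e$duration, e$amplitude, spec$tr, nt)
        conv <- stats::convolve(c(train, numeric(length(kern))),
                                rev(kern), type = "open")
        conv <- conv[seq_len(nt)] * spec$tr
        loading <- if (is.na(e$mapping[1])) rep(1, reg$n_voxels)
                   else 1 + reg$pattern_gain *
                        reg$patterns[[e$task[1]]][e$mapping[1], ]
        sig[, cols] <- sig[, cols] + conv %o% loading
      }
    }
    col0 <- col0 + reg$n_voxels
  }
  drift_basis <- legendre_basis(nt, 3)
  pct <- sig
  for (v in seq_len(nv_total)) {
    drift <- drift_basis %*% stats::rnorm(3, 0, noise$drift_sd)
    pct[, v] <- pct[, v] + drift + ar1_noise(nt, noise$sigma, noise$phi)
  }
  nuis <- matrix(0, nt, 0)
  if (noise$n_nuisance > 0) {
    tt <- seq_len(nt) / nt
    nuis <- sapply(seq_len(noise$n_nuisance), function(j)
      sin(2 * pi * (j * 1.5 * tt + stats::runif(1))))
    nuis <- matrix(nuis, nt)
    loadings <- matrix(stats::rnorm(noise$n_nuisance * nv_total, 0,
                                    noise$nuisance_sd),
                       noise$n_nuisance, nv_total)
    pct <- pct + nuis %*% loadings
  }
  base <- noise$base_level * stats::runif(nv_total, 0.9, 1.1)
  raw <- sweep(1 + pct / 100, 2, base, "*")
  out <- bold_run(raw, spec$tr, run = trials$run[1], roi_labels = labels,
                  nuisance = nuis)
  attr(out, "signal") <- sig
  out
}

#' Simulate a full synthetic subject
#'
#' Design, behavior (one subject-level central-stage scale), and BOLD runs
#' for a region set.
#'
#' @param spec a \code{\link{design_spec}}.
#' @param regions named list of \code{\link{region_model}}s.
#' @param model a \code{\link{stage_model}}.
#' @param noise a \code{\link{noise_config}}.
#' @param c_scale optional fixed subject central-stage scale.
#' @return List with \code{trials} (all runs, behavior filled),
#'   \code{runs} (list of \code{\link{bold_run}}), \code{c_scale}, and
#'   \code{behavior} (the \code{\link{summarize_behavior}} summary).
#' @export
simulate_subject <- function(spec, regions, model = stage_model(),
                             noise = noise_config(), c_scale = NULL) {
  trials <- make_design(spec)
  trials <- simulate_behavior(trials, model, c_scale = c_scale)
  runs <- lapply(split(trials, trials$run), function(tr_run)
    synthesize_bold(tr_run, regions, spec, noise))
  names(runs) <- NULL
  list(trials = trials, runs = runs,
       c_scale = attr(trials, "c_scale"),
       behavior = summarize_behavior(trials))
}
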