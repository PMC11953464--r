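# Shared helpers for the multi-run deconvolution models: per-run drift and
# nuisance blocks, FIR sets per trial group, censor/segment bookkeeping.

run_drift_block <- function(run, drift_order = 3) {
  n <- nrow(run$data)
  cbind(intercept = rep(1, n),
        legendre_basis(n, drift_order),
        run$nuisance)
}

# block-diagonal column binding of per-run matrices
bdiag_rows <- function(blocks) {
  nr <- vapply(blocks, nrow, 0L)
  nc <- vapply(blocks, ncol, 0L)
  out <- matrix(0, sum(nr), sum(nc))
  r0 <- 0L; c0 <- 0L
  for (b in blocks) {
    if (ncol(b))
      out[r0 + seq_len(nrow(b)), c0 + seq_len(ncol(b))] <- b
    r0 <- r0 + nrow(b); c0 <- c0 + ncol(b)
  }
  out
}

roi_columns <- function(run, roi) {
  if (is.null(roi)) seq_along(run$roi_labels)
  else which(run$roi_labels %in% roi)
}

ensure_scaled <- function(runs) {
  lapply(runs, function(r) if (isTRUE(attr(r, "scaled"))) r
                           else scale_percent(r))
}

#' Condition (or group) timecourses by shape-free deconvolution
#'
#' Fits one finite-impulse-response set per trial group (by default the
#' six task conditions; pass \code{groups} for variants such as
#' RT-quartile splits) to the concatenated runs, with incorrect trials
#' modeled by their own FIR set, per-run intercept + polynomial drift +
#' nuisance columns, censoring, and AR(1) prewhitening. Voxel betas are
#' averaged across the ROI after estimation.
#'
#' @param runs list of \code{\link{bold_run}}s (percent-scaled
#'   automatically if needed).
#' @param trials trial table covering those runs (with \code{correct}).
#' @param window_points FIR window length in TRs (default 69).
#' @param roi ROI label(s) to average over (NULL = all voxels).
#' @param groups character per trial defining the regressor sets (default
#'   \code{trials$condition}).
#' @param drift_order per-run Legendre drift order.
#' @param ar_pool passed to \code{\link{fit_glm_prewhitened}}.
#' @return Named list of \code{condition_timecourse} objects: lists with
#'   \code{condition}, \code{time} (s from trial onset), \code{values}
#'   (ROI-mean percent signal per lag), \code{voxel_betas}
#'   (lag-by-voxel), \code{n_trials}. Groups with no correct trials are
#'   absent, with a warning.
#' @export
estimate_condition_timecourses <- function(runs, trials, window_points = 69,
                                           roi = NULL, groups = NULL,
                                           drift_order = 3,
                                           ar_pool = "pooled") {
  runs <- ensure_scaled(runs)
  tr <- runs[[1]]$tr
  if (is.null(groups)) groups <- trials$condition
  trials$.group <- groups
  glev <- unique(groups)
  run_ids <- vapply(runs, function(r) r$run, 0)
  empty <- character(0)
  Xg_list <- list(); Xn_list <- list()
  for (ri in seq_along(runs)) {
    tr_run <- trials[trials$run == run_ids[ri], , drop = FALSE]
    nvol <- nrow(runs[[ri]]$data)
    cols <- lapply(glev, function(g) {
      on <- tr_run$onset_t1[tr_run$.group == g & tr_run$correct]
      suppressWarnings(build_fir_basis(on, window_points, tr, nvol))
    })
    bad_on <- tr_run$onset_t1[!tr_run$correct]
    Xbad <- suppressWarnings(build_fir_basis(bad_on, window_points, tr, nvol))
    Xg_list[[ri]] <- do.call(cbind, cols)
    Xn_list[[ri]] <- cbind(Xbad, run_drift_block(runs[[ri]], drift_order))
  }
  Xg <- do.call(rbind, Xg_list)
  Xn <- bdiag_rows(Xn_list)
  keep_bad <- colSums(abs(Xn)) > 0
  X <- cbind(Xg, Xn[, keep_bad, drop = FALSE])
  vox <- roi_columns(runs[[1]], roi)
  Y <- do.call(rbind, lapply(runs, function(r) r$data[, vox, drop = FALSE]))
  segments <- rep(seq_along(runs),
                  vapply(runs, function(r) nrow(r$data), 0L))
  censor <- unlist(lapply(runs, function(r) r$censor))
  fit <- fit_glm_prewhitened(Y, X, censor = censor, segments = segments,
                             ar_pool = ar_pool)
  out <- list()
  for (gi in seq_along(glev)) {
    g <- glev[gi]
    n_tr <- sum(trials$.group == g & trials$correct)
    if (n_tr == 0) { empty <- c(empty, g); next }
    rows <- (gi - 1) * window_points + seq_len(window_points)
    vb <- fit$betas[rows, , drop = FALSE]
    out[[g]] <- structure(list(condition = g,
                               time = (seq_len(window_points) - 1) * tr,
                               values = rowMeans(vb),
                               voxel_betas = vb, n_trials = n_tr),
                          class = "condition_timecourse")
  }
  if (length(empty))
    warning("no correct trials for: ", paste(empty, collapse = ", "))
  out
}

#' Trial-wise response patterns (simultaneous whole-event regressors)
#'
#' Estimates one beta map per correct single-task trial: every such trial
#' gets its own HRF-convolved whole-event regressor, fitted jointly per
#' run together with pooled regressors for each dual-task condition,
#' a pooled regressor for incorrect trials, and drift/nuisance columns.
#' These per-trial patterns are the training data for the pattern
#' classifiers.
#'
#' @param runs list of \code{\link{bold_run}}s.
#' @param trials trial table.
#' @param hrf an \code{\link{hrf_params}} for the whole-event regressors.
#' @param roi ROI label(s) (NULL = all voxels).
#' @param tasks single-task conditions to estimate (default both).
#' @param drift_order per-run drift order.
#' @param cond_warn condition-number threshold for a near-collinearity
#'   warning.
#' @return List: \code{betas} (trial-by-voxel), \code{trials} (matching
#'   rows: run, trial, condition/task, mapping).
#' @export
estimate_trial_betas <- function(runs, trials, hrf = hrf_params(),
                                 roi = NULL, tasks = c("AO", "VM"),
                                 drift_order = 3, cond_warn = 1e6) {
  runs <- ensure_scaled(runs)
  tr <- runs[[1]]$tr
  run_ids <- vapply(runs, function(r) r$run, 0)
  vox <- roi_columns(runs[[1]], roi)
  beta_list <- list(); info_list <- list()
  for (ri in seq_along(runs)) {
    tr_run <- trials[trials$run == run_ids[ri], , drop = FALSE]
    nvol <- nrow(runs[[ri]]$data)
    tgt <- which(tr_run$condition %in% tasks & tr_run$correct)
    if (!length(tgt)) next
    Xt <- sapply(tgt, function(i)
      build_event_regressor(tr_run$onset_t1[i], hrf, tr, nvol))
    Xt <- matrix(Xt, nvol)
    dualc <- setdiff(unique(tr_run$condition), tasks)
    Xd <- if (length(dualc)) {
      matrix(sapply(dualc, function(cc) {
        on <- tr_run$onset_t1[tr_run$condition == cc & tr_run$correct]
        if (!length(on)) return(numeric(nvol))
        build_event_regressor(on, hrf, tr, nvol)
      }), nvol)
    } else matrix(0, nvol, 0)
    bad_on <- tr_run$onset_t1[!tr_run$correct]
    Xb <- if (length(bad_on))
      build_event_regressor(bad_on, hrf, tr, nvol) else NULL
    X <- cbind(Xt, Xd[, colSums(abs(Xd)) > 0, drop = FALSE], Xb,
               run_drift_block(runs[[ri]], drift_order))
    kappa_est <- kappa(qr.R(qr(scale(X, center = FALSE))), exact = FALSE)
    if (is.finite(kappa_est) && kappa_est > cond_warn)
      warning(sprintf("near-collinear trial regressors in run %s (cond. number %.3g)",
                      format(run_ids[ri]), kappa_est))
    fit <- fit_glm_prewhitened(runs[[ri]]$data[, vox, drop = FALSE], X,
                               censor = runs[[ri]]$censor)
    beta_list[[ri]] <- fit$betas[seq_along(tgt), , drop = FALSE]
    info_list[[ri]] <- tr_run[tgt, c("run", "trial", "condition", "task1",
                                     "map1", "rt1")]
  }
  betas <- do.call(rbind, beta_list)
  info <- do.call(rbind, info_list)
  rownames(betas) <- NULL; rownames(info) <- NULL
  list(betas = betas, trials = info)
}

#' Trial-wise signal-change timecourses by least-squares-sum estimation
#'
#' For each correct trial of a target condition, fits a model holding a
#' 69-point FIR set for that trial, a second shared FIR set for all other
#' correct trials of the same condition, one shared FIR set per other
#' condition, an FIR set for incorrect trials, and drift/nuisance columns;
#' returns the target trial's FIR betas. Repeating per trial yields a
#' signal-change timecourse for every trial, the input to time-resolved
#' decoding. Conditions with a single correct trial fall back to the plain
#' FIR estimate with a warning.
#'
#' @param runs list of \code{\link{bold_run}}s.
#' @param trials trial table.
#' @param window_points FIR window (default 69).
#' @param target_conditions conditions to estimate trial-wise (default:
#'   all present).
#' @param roi ROI label(s).
#' @param drift_order per-run drift order.
#' @return Named list per condition: \code{time}, \code{trials} (rows:
#'   run, trial, condition, tasks, mappings, soa), \code{betas} (array
#'   lag x voxel x trial).
#' @export
estimate_trialwise_timecourses_lss <- function(runs, trials,
                                               window_points = 69,
                                               target_conditions = NULL,
                                               roi = NULL,
                                               drift_order = 3) {
  runs <- ensure_scaled(runs)
  tr <- runs[[1]]$tr
  run_ids <- vapply(runs, function(r) r$run, 0)
  vox <- roi_columns(runs[[1]], roi)
  if (is.null(target_conditions))
    target_conditions <- unique(trials$condition)
  out <- list()
  keep_cols <- c("run", "trial", "condition", "task1", "task2", "soa",
                 "map1", "map2")
  for (cc in target_conditions) {
    betas <- list(); info <- list()
    for (ri in seq_along(runs)) {
      tr_run <- trials[trials$run == run_ids[ri], , drop = FALSE]
      nvol <- nrow(runs[[ri]]$data)
      keep <- which(runs[[ri]]$censor)
      Y <- runs[[ri]]$data[keep, vox, drop = FALSE]
      base_fir <- lapply(setdiff(unique(tr_run$condition), cc), function(g) {
        on <- tr_run$onset_t1[tr_run$condition == g & tr_run$correct]
        suppressWarnings(build_fir_basis(on, window_points, tr, nvol))
      })
      bad_on <- tr_run$onset_t1[!tr_run$correct]
      Xfix <- cbind(do.call(cbind, base_fir),
                    suppressWarnings(
                      build_fir_basis(bad_on, window_points, tr, nvol)),
                    run_drift_block(runs[[ri]], drift_order))
      Xfix <- Xfix[, colSums(abs(Xfix)) > 0, drop = FALSE]
      tgt <- which(tr_run$condition == cc & tr_run$correct)
      if (!length(tgt)) next
      all_on <- tr_run$onset_t1[tgt]
      cond_fir <- suppressWarnings(
        build_fir_basis(all_on, window_points, tr, nvol))
      if (length(tgt) == 1)
        warning("single correct trial in condition ", cc,
                "; plain FIR estimate used")
      for (j in seq_along(tgt)) {
        Xt <- suppressWarnings(
          build_fir_basis(all_on[j], window_points, tr, nvol))
        Xo <- cond_fir - Xt
        X <- if (length(tgt) > 1) cbind(Xt, Xo, Xfix) else cbind(Xt, Xfix)
        Xk <- X[keep, , drop = FALSE]
        nz <- colSums(abs(Xk)) > 0   # run-end truncation empties late lags
        Xnz <- Xk[, nz, drop = FALSE]
        cf_nz <- tryCatch(
          chol2inv(chol(crossprod(Xnz))) %*% crossprod(Xnz, Y),
          error = function(e) tryCatch(
            qr.coef(qr(Xnz, LAPACK = TRUE), Y),
            error = function(e2)  # rank deficiency: LINPACK flags NA rows
              qr.coef(qr(Xnz), Y)))
        cf <- matrix(NA_real_, ncol(X), ncol(Y))
        cf[nz, ] <- cf_nz
        betas[[length(betas) + 1]] <-
          matrix(cf[seq_len(window_points), ], window_points,
                 dimnames = NULL)
        info[[length(info) + 1]] <- tr_run[tgt[j], keep_cols]
      }
    }
    if (!length(betas)) next
    arr <- array(unlist(betas),
                 dim = c(window_points, length(vox), length(betas)))
    out[[cc]] <- list(condition = cc,
                      time = (seq_len(window_points) - 1) * tr,
                      trials = do.call(rbind, info), betas = arr)
  }
  out
}
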