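#' Percent-signal scaling
#'
#' Divides each voxel by its temporal mean and multiplies by 100, so that
#' regression effect estimates read as percent signal change; the
#' post-scaling temporal mean of every voxel is exactly 100. Voxels with
#' non-positive mean cannot be scaled and are flagged and excluded.
#'
#' @param run a \code{\link{bold_run}}.
#' @return The run with scaled \code{data}; indices of excluded voxels (if
#'   any) in attribute \code{"excluded"}.
#' @export
scale_percent <- function(run) {
  stopifnot(inherits(run, "bold_run"))
  mu <- colMeans(run$data)
  bad <- which(mu <= 0)
  if (length(bad)) {
    warning(length(bad), " voxel(s) with non-positive mean excluded")
    run$data <- run$data[, -bad, drop = FALSE]
    run$roi_labels <- run$roi_labels[-bad]
    mu <- mu[-bad]
  }
  run$data <- sweep(run$data, 2, mu / 100, "/")
  attr(run, "excluded") <- if (length(bad)) bad else integer(0)
  attr(run, "scaled") <- TRUE
  run
}

#' Finite-impulse-response (shape-free) basis columns
#'
#' One indicator column per post-onset lag \code{k = 0..window_points-1};
#' column k carries a 1 at volume(onset) + k for every onset (overlapping
#' trials sum). Onsets are snapped to the TR grid by rounding. The default
#' 69-point window at TR 199 ms spans stimulus onset to about 13.5 s,
#' matching a 69-estimate shape-free deconvolution.
#'
#' @param onsets event onsets (s).
#' @param window_points number of lags (default 69).
#' @param tr repetition time (s).
#' @param n_volumes run length (volumes).
#' @return n_volumes-by-window_points matrix; lags extending past the run
#'   end are truncated with a warning.
#' @export
build_fir_basis <- function(onsets, window_points = 69, tr, n_volumes) {
  X <- matrix(0, n_volumes, window_points)
  if (!length(onsets)) return(X)
  v0 <- round(onsets / tr) + 1L
  truncated <- FALSE
  for (v in v0) {
    idx <- v + seq_len(window_points) - 1L
    keep <- idx <= n_volumes & idx >= 1L
    if (!all(keep)) truncated <- TRUE
    X[cbind(idx[keep], which(keep))] <-
      X[cbind(idx[keep], which(keep))] + 1
  }
  if (truncated)
    warning("FIR window extends beyond run end; truncated")
  X
}

#' Whole-event regressor: delta or boxcar train convolved with an HRF
#'
#' @param onsets event onsets (s).
#' @param hrf an \code{\link{hrf_params}}.
#' @param tr repetition time (s).
#' @param n_volumes run length.
#' @param durations optional event durations (s); 0 (default) gives a
#'   delta train (impulse events), positive values a boxcar train.
#' @return Numeric regressor of length \code{n_volumes}. Delta events are
#'   normalized so a single event reproduces the HRF samples exactly;
#'   boxcar events integrate the HRF over the event (time step = TR).
#' @export
build_event_regressor <- function(onsets, hrf, tr, n_volumes,
                                  durations = 0) {
  stopifnot(inherits(hrf, "hrf_params"))
  durations <- rep_len(durations, length(onsets))
  kern <- hrf_kernel(hrf, tr, duration = 30)
  if (all(durations == 0)) {
    train <- numeric(n_volumes)
    v0 <- round(onsets / tr) + 1L
    v0 <- v0[v0 >= 1 & v0 <= n_volumes]
    for (v in v0) train[v] <- train[v] + 1
    scale <- 1
  } else {
    train <- event_train(onsets, durations, rep(1, length(onsets)),
                         tr, n_volumes)
    scale <- tr
  }
  conv <- stats::convolve(c(train, numeric(length(kern))), rev(kern),
                          type = "open")
  conv[seq_len(n_volumes)] * scale
}

# AR(1) quasi-differencing: rows whitened in place, first row of each
# segment scaled by sqrt(1 - rho^2)
whiten_ar1 <- function(M, rho, segments) {
  M <- as.matrix(M)
  out <- M
  for (s in unique(segments)) {
    idx <- which(segments == s)
    if (length(idx) > 1)
      out[idx[-1], ] <- M[idx[-1], , drop = FALSE] -
        rho * M[idx[-length(idx)], , drop = FALSE]
    out[idx[1], ] <- sqrt(1 - rho^2) * M[idx[1], , drop = FALSE]
  }
  out
}

#' Prewhitened (AR(1) feasible GLS) multi-voxel regression
#'
#' Censored volumes are removed from data and design; ordinary least
#' squares residuals provide a lag-1 autocorrelation estimate per voxel
#' (within run segments); data and design are then quasi-differenced and
#' refitted. With \code{ar_pool = "pooled"} (default) a single
#' voxel-averaged coefficient whitens all voxels at once, which is the
#' appropriate choice for ROI-level analyses and allows one multi-RHS
#' factorization; \code{"voxel"} whitens each voxel with its own
#' coefficient.
#'
#' @param Y time-by-voxel data matrix (or \code{\link{bold_run}}).
#' @param X design matrix (time-by-regressors).
#' @param censor logical keep flag per volume (default: keep all, or the
#'   run's own censor when \code{Y} is a \code{bold_run}).
#' @param segments run/segment id per volume (AR estimation and whitening
#'   never cross segments); default: one segment.
#' @param ar_pool \code{"pooled"} or \code{"voxel"}.
#' @param contrasts optional numeric matrix (rows = contrasts over
#'   regressors) for t-statistics.
#' @return List of class \code{"beta_estimates"}: \code{betas}
#'   (regressors-by-voxels), \code{sigma2}, \code{ar_coeff},
#'   \code{tstats} (contrasts-by-voxels or NULL), \code{df_residual}.
#' @export
fit_glm_prewhitened <- function(Y, X, censor = NULL, segments = NULL,
                                ar_pool = c("pooled", "voxel"),
                                contrasts = NULL) {
  ar_pool <- match.arg(ar_pool)
  if (inherits(Y, "bold_run")) {
    if (is.null(censor)) censor <- Y$censor
    Y <- Y$data
  }
  Y <- as.matrix(Y); X <- as.matrix(X)
  stopifnot(nrow(Y) == nrow(X))
  n <- nrow(X)
  if (is.null(censor)) censor <- rep(TRUE, n)
  if (is.null(segments)) segments <- rep(1L, n)
  keep <- which(censor)
  Y <- Y[keep, , drop = FALSE]
  X <- X[keep, , drop = FALSE]
  segments <- segments[keep]
  # all-zero columns (e.g., empty trial groups, truncated lags) carry no
  # information: fit without them, report NA betas in their place
  nz <- colSums(abs(X)) > 0
  if (!all(nz)) {
    full_p <- ncol(X)
    full_names <- colnames(X)
    sub <- fit_glm_prewhitened(Y, X[, nz, drop = FALSE],
                               segments = segments, ar_pool = ar_pool)
    betas <- matrix(NA_real_, full_p, ncol(Y))
    betas[nz, ] <- sub$betas
    rownames(betas) <- full_names
    tstats <- NULL
    if (!is.null(contrasts)) {
      L <- matrix(contrasts, ncol = full_p)
      sub_t <- fit_glm_prewhitened(Y, X[, nz, drop = FALSE],
                                   segments = segments, ar_pool = ar_pool,
                                   contrasts = L[, nz, drop = FALSE])
      tstats <- sub_t$tstats
    }
    return(structure(list(betas = betas, sigma2 = sub$sigma2,
                          ar_coeff = sub$ar_coeff, tstats = tstats,
                          df_residual = sub$df_residual,
                          dropped_columns = which(!nz)),
                     class = "beta_estimates"))
  }
  solve_ls <- function(Xw, Yw) {
    # normal equations via Cholesky (fast for these tall designs); a
    # pivoted-QR fallback diagnoses genuine rank deficiency
    f <- tryCatch({
      R <- chol(crossprod(Xw))
      XtXi <- chol2inv(R)
      list(B = XtXi %*% crossprod(Xw, Yw), XtXi = XtXi)
    }, error = function(e) NULL)
    if (is.null(f)) {
      q <- qr(Xw, LAPACK = TRUE)  # column-pivoted
      rdiag <- abs(diag(qr.R(q)))
      rank <- sum(rdiag > max(rdiag) * max(dim(Xw)) * 1e-12)
      if (rank < ncol(Xw)) {
        dropped <- q$pivot[(rank + 1):ncol(Xw)]
        nm <- colnames(Xw)
        stop("rank-deficient design; collinear columns: ",
             paste(if (is.null(nm)) dropped else nm[dropped],
                   collapse = ", "))
      }
      XtXi <- chol2inv(qr.R(q))[order(q$pivot), order(q$pivot),
                                drop = FALSE]
      f <- list(B = qr.coef(q, Yw), XtXi = XtXi)
    }
    f
  }
  B0 <- solve_ls(X, Y)$B
  E <- Y - X %*% B0
  shift_ok <- segments[-1] == segments[-length(segments)]
  num <- colSums(E[-1, , drop = FALSE][shift_ok, , drop = FALSE] *
                 E[-nrow(E), , drop = FALSE][shift_ok, , drop = FALSE])
  den <- colSums(E^2)
  rho <- ifelse(den > 0, num / den, 0)
  rho <- pmin(pmax(rho, -0.99), 0.99)
  p <- ncol(X)
  dfres <- nrow(X) - p
  fit_one <- function(Xw, Yw) {
    f <- solve_ls(Xw, Yw)
    E2 <- Yw - Xw %*% f$B
    list(B = f$B, s2 = colSums(E2^2) / dfres, XtXi = f$XtXi)
  }
  if (ar_pool == "pooled") {
    r <- mean(rho)
    f <- fit_one(whiten_ar1(X, r, segments), whiten_ar1(Y, r, segments))
    betas <- f$B; sigma2 <- f$s2
    cvar <- function(l) drop(t(l) %*% f$XtXi %*% l)
    rho_out <- rep(r, ncol(Y))
    tstat_fun <- function(L) {
      t(apply(L, 1, function(l) drop(l %*% betas) / sqrt(cvar(l) * sigma2)))
    }
  } else {
    betas <- matrix(NA_real_, p, ncol(Y))
    sigma2 <- numeric(ncol(Y))
    xtxi_list <- vector("list", ncol(Y))
    for (v in seq_len(ncol(Y))) {
      f <- fit_one(whiten_ar1(X, rho[v], segments),
                   whiten_ar1(Y[, v, drop = FALSE], rho[v], segments))
      betas[, v] <- f$B; sigma2[v] <- f$s2; xtxi_list[[v]] <- f$XtXi
    }
    rho_out <- rho
    tstat_fun <- function(L) {
      out <- matrix(NA_real_, nrow(L), ncol(Y))
      for (v in seq_len(ncol(Y))) {
        cv <- apply(L, 1, function(l) drop(t(l) %*% xtxi_list[[v]] %*% l))
        out[, v] <- drop(L %*% betas[, v]) / sqrt(cv * sigma2[v])
      }
      out
    }
  }
  rownames(betas) <- colnames(X)
  tstats <- NULL
  if (!is.null(contrasts)) {
    L <- matrix(contrasts, ncol = p)
    tstats <- tstat_fun(L)
  }
  structure(list(betas = betas, sigma2 = sigma2, ar_coeff = rho_out,
                 tstats = tstats, df_residual = dfres),
            class = "beta_estimates")
}
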