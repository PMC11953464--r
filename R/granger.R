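# Multi-trial vector autoregression and time-domain pairwise-conditional
# Granger causality over ROI timecourses. Each trial's timecourse is a
# separate segment; lagged predictors never cross segment boundaries.

# stack lagged design over segments: rows = usable time points
var_design <- function(segments, p) {
  Xs <- list(); Ys <- list()
  for (seg in segments) {
    seg <- as.matrix(seg)
    n <- nrow(seg)
    if (n <= p) next
    idx <- (p + 1):n
    lags <- do.call(cbind, lapply(seq_len(p), function(l)
      seg[idx - l, , drop = FALSE]))
    Xs[[length(Xs) + 1]] <- lags
    Ys[[length(Ys) + 1]] <- seg[idx, , drop = FALSE]
  }
  if (!length(Xs)) stop("insufficient samples: all segments shorter than p")
  list(X = do.call(rbind, Xs), Y = do.call(rbind, Ys))
}

# residual covariance of a VAR(p) least-squares fit (optionally omitting
# one channel's lags from the predictors)
var_resid_cov <- function(segments, p, omit = NULL, demean = TRUE) {
  if (demean)
    segments <- lapply(segments, function(s) scale(s, scale = FALSE))
  d <- var_design(segments, p)
  m <- ncol(d$Y)
  keep <- rep(TRUE, ncol(d$X))
  if (!is.null(omit))
    keep[rep(seq_len(m), p) == omit] <- FALSE
  X <- cbind(1, d$X[, keep, drop = FALSE])
  B <- qr.coef(qr(X, LAPACK = TRUE), d$Y)
  E <- d$Y - X %*% B
  # ML divisor: keeps nested residual-variance ratios >= 1, so GC >= 0
  list(Sigma = crossprod(E) / nrow(E), B = B, n = nrow(E))
}

#' Select the VAR model order by AIC
#'
#' Fits pooled multi-segment VAR models of order 1..p_max and returns the
#' order minimizing the Akaike information criterion
#' (\code{log det Sigma + 2 p m^2 / n}).
#'
#' @param segments list of time-by-ROI matrices (one per trial).
#' @param p_max maximum order (default 10).
#' @return Integer order; per-order AIC in attribute \code{"aic"}.
#' @export
select_var_order <- function(segments, p_max = 10) {
  segments <- lapply(segments, as.matrix)
  m <- ncol(segments[[1]])
  nmin <- min(vapply(segments, nrow, 0L))
  if (nmin <= p_max)
    stop("segment length ", nmin, " must exceed p_max = ", p_max)
  aic <- sapply(seq_len(p_max), function(p) {
    f <- var_resid_cov(segments, p)
    determinant(f$Sigma, logarithm = TRUE)$modulus + 2 * p * m^2 / f$n
  })
  p <- which.min(aic)
  attr(p, "aic") <- aic
  p
}

#' Fit a multi-segment VAR model
#'
#' Pooled least squares over all segments with lags confined within
#' segments; per-trial means removed by default. Stability is assessed
#' from the spectral radius of the companion matrix.
#'
#' @param segments list of time-by-ROI matrices.
#' @param p model order (>= 1).
#' @param demean remove each segment's channel means (default TRUE).
#' @return Object of class \code{"var_model"}: \code{A} (list of p
#'   ROI-by-ROI coefficient matrices), \code{Sigma} (residual
#'   covariance), \code{p}, \code{n_rois}, \code{stable},
#'   \code{spectral_radius}.
#' @export
fit_var <- function(segments, p, demean = TRUE) {
  stopifnot(p >= 1)
  segments <- lapply(segments, as.matrix)
  m <- ncol(segments[[1]])
  f <- var_resid_cov(segments, p, demean = demean)
  # B rows: intercept, then lag-1 channels, lag-2 channels, ...
  A <- lapply(seq_len(p), function(l)
    t(f$B[1 + (l - 1) * m + seq_len(m), , drop = FALSE]))
  comp <- matrix(0, m * p, m * p)
  comp[seq_len(m), ] <- do.call(cbind, A)
  if (p > 1)
    comp[(m + 1):(m * p), seq_len(m * (p - 1))] <- diag(m * (p - 1))
  sr <- max(Mod(eigen(comp, only.values = TRUE)$values))
  structure(list(A = A, Sigma = f$Sigma, p = p, n_rois = m,
                 stable = sr < 1, spectral_radius = sr),
            class = "var_model")
}

#' Time-domain pairwise-conditional Granger causality
#'
#' For every directed pair (i -> j), the log-ratio of the target's
#' residual variance in the reduced model (channel i's lags omitted, all
#' other channels retained as conditioning set) to its residual variance
#' in the full VAR: \code{F[i,j] = log(var_reduced / var_full)}.
#'
#' @param segments list of time-by-ROI matrices.
#' @param p VAR order (e.g., from \code{\link{select_var_order}}).
#' @param demean remove per-segment means (default TRUE).
#' @return Object of class \code{"gc_result"}: matrix \code{F} with
#'   \code{F[i, j]} = GC from ROI i to ROI j (diagonal NA), \code{order},
#'   \code{rois}.
#' @export
pairwise_conditional_gc <- function(segments, p, demean = TRUE) {
  segments <- lapply(segments, as.matrix)
  m <- ncol(segments[[1]])
  if (m < 2) stop("need at least 2 ROIs")
  rois <- colnames(segments[[1]])
  if (is.null(rois)) rois <- paste0("roi", seq_len(m))
  full <- var_resid_cov(segments, p, demean = demean)
  Fm <- matrix(NA_real_, m, m, dimnames = list(rois, rois))
  for (i in seq_len(m)) {
    red <- var_resid_cov(segments, p, omit = i, demean = demean)
    for (j in seq_len(m)[-i])
      Fm[i, j] <- log(red$Sigma[j, j] / full$Sigma[j, j])
  }
  structure(list(F = Fm, order = p, rois = rois), class = "gc_result")
}

#' Compare Granger causality between conditions across subjects
#'
#' Paired t test per directed connection between two matched sets of GC
#' matrices (e.g., preferred-task vs control-task single-task conditions),
#' with Cohen's d and optional Benjamini-Hochberg adjustment.
#'
#' @param gc_a,gc_b lists of \code{gc_result} (or plain matrices), one
#'   per subject, matched order.
#' @param fdr apply BH adjustment over the off-diagonal connections.
#' @return data.frame: from, to, mean_diff, t, df, p, (p_adj,) cohens_d.
#' @export
compare_gc_conditions <- function(gc_a, gc_b, fdr = TRUE) {
  getF <- function(g) if (inherits(g, "gc_result")) g$F else g
  Fa <- lapply(gc_a, getF); Fb <- lapply(gc_b, getF)
  if (length(Fa) != length(Fb)) stop("subject lists must be matched")
  if (length(Fa) < 3) stop("need at least 3 subjects")
  m <- nrow(Fa[[1]])
  rois <- rownames(Fa[[1]])
  if (is.null(rois)) rois <- paste0("roi", seq_len(m))
  rows <- NULL
  for (i in seq_len(m)) for (j in seq_len(m)[-i]) {
    a <- vapply(Fa, function(x) x[i, j], 0)
    b <- vapply(Fb, function(x) x[i, j], 0)
    tt <- paired_t(a, b)
    rows <- rbind(rows, data.frame(
      from = rois[i], to = rois[j], mean_diff = mean(a - b),
      t = tt$statistic, df = tt$dof, p = tt$p, cohens_d = tt$effect_size))
  }
  if (fdr) rows$p_adj <- bh_fdr(rows$p)
  rows
}
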