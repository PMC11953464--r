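# Group-level inferential helpers: paired t with Cohen's d, one-way
# repeated-measures ANOVA with partial eta^2, Pearson correlation,
# Benjamini-Hochberg FDR, and a JZS Bayes factor for null support.

#' Paired-sample t test with Cohen's d
#'
#' Classical paired t (via \code{\link[stats]{t.test}}) with the
#' difference-score effect size d = mean(diff)/sd(diff).
#'
#' @param x,y paired observations (equal length, n >= 2).
#' @param tails 2 (default) or 1 (one-tailed, direction of the observed
#'   mean difference halves the two-tailed p).
#' @return List of class \code{"test_result"}: \code{statistic},
#'   \code{dof}, \code{p}, \code{effect_size} (Cohen's d),
#'   \code{tails}, \code{n}. A zero-variance difference yields an
#'   infinite-t flag.
#' @export
paired_t <- function(x, y, tails = 2) {
  stopifnot(length(x) == length(y), length(x) >= 2, tails %in% c(1, 2))
  d <- x - y
  if (stats::sd(d) == 0) {
    return(structure(list(statistic = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                          dof = length(d) - 1,
                          p = if (mean(d) == 0) 1 else 0,
                          effect_size = NA_real_, tails = tails,
                          n = length(d), zero_variance = TRUE),
                     class = "test_result"))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  p <- tt$p.value
  if (tails == 1) p <- p / 2
  structure(list(statistic = unname(tt$statistic), dof = unname(tt$parameter),
                 p = p, effect_size = mean(d) / stats::sd(d),
                 tails = tails, n = length(d)),
            class = "test_result")
}

#' One-way repeated-measures ANOVA with partial eta squared
#'
#' Within-subject F for a subjects-by-conditions matrix:
#' F(k-1, (k-1)(n-1)) with partial eta^2 =
#' SS_effect / (SS_effect + SS_error). For two conditions, F equals the
#' squared paired t.
#'
#' @param M numeric matrix, rows = subjects (>= 3), columns = conditions
#'   (>= 2); no missing cells.
#' @return \code{test_result} list: \code{statistic} (F), \code{dof}
#'   (length 2), \code{p}, \code{effect_size} (partial eta^2), \code{n}.
#' @export
rm_anova <- function(M) {
  M <- as.matrix(M)
  if (anyNA(M)) stop("missing cells are not supported")
  n <- nrow(M); k <- ncol(M)
  stopifnot(n >= 3, k >= 2)
  grand <- mean(M)
  ss_cond <- n * sum((colMeans(M) - grand)^2)
  ss_subj <- k * sum((rowMeans(M) - grand)^2)
  ss_tot <- sum((M - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  Fv <- if (ss_err <= 1e-300) {
    if (ss_cond <= 1e-300) 0 else Inf   # degenerate: no residual variance
  } else (ss_cond / df1) / (ss_err / df2)
  structure(list(statistic = Fv, dof = c(df1, df2),
                 p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
                 effect_size = ss_cond / (ss_cond + ss_err),
                 tails = NA, n = n),
            class = "test_result")
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up false-discovery-rate adjustment (monotone), via
#' \code{\link[stats]{p.adjust}}.
#'
#' @param pvalues raw p values in [0, 1].
#' @param q optional threshold; when given, attribute \code{"reject"}
#'   flags the rejection set at level q.
#' @return Adjusted p values (same order as input).
#' @export
bh_fdr <- function(pvalues, q = NULL) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  adj <- stats::p.adjust(pvalues, method = "BH")
  if (!is.null(q)) attr(adj, "reject") <- adj <= q
  adj
}

#' Pearson correlation with two-tailed p
#'
#' @param x,y numeric vectors (n >= 3, non-zero variance).
#' @return List: \code{r}, \code{p}, \code{n}.
#' @export
pearson_corr <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' JZS Bayes factor for the null (one-sample / paired t)
#'
#' Jeffreys-Zellner-Siow Bayes factor BF01 (null over alternative) for a
#' one-sample or paired t statistic, with a Cauchy prior of scale
#' r = sqrt(2)/2 on the standardized effect, computed by numerical
#' integration over the g mixture (Rouder et al. formulation).
#'
#' @param t observed t statistic.
#' @param n sample size (pairs), >= 2.
#' @param r Cauchy prior scale (default sqrt(2)/2).
#' @param rel.tol integration tolerance.
#' @return BF01 (values > 1 favor the null).
#' @export
jzs_bf01 <- function(t, n, r = sqrt(2) / 2, rel.tol = 1e-10) {
  stopifnot(n >= 2)
  nu <- n - 1
  null_dens <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  integrand <- function(g)
    (1 + n * g)^(-1 / 2) *
      (1 + t^2 / ((1 + n * g) * nu))^(-(nu + 1) / 2) *
      (2 * pi)^(-1 / 2) * r * g^(-3 / 2) * exp(-r^2 / (2 * g))
  alt <- tryCatch(
    stats::integrate(integrand, 0, Inf, rel.tol = rel.tol,
                     abs.tol = 0)$value,
    error = function(e) stop("integration failure: ", conditionMessage(e)))
  null_dens / alt
}
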