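# Pattern classification: feature selection, one-vs-rest L2 logistic
# regression (penalty 25), leave-one-run-out CV, cross-task tests, and
# time-resolved decoding of trial-wise timecourses.

#' Per-voxel activation t-maps from trial-wise patterns
#'
#' One-sample t statistic of each voxel's trial betas against zero,
#' computed per task; the feature-selection input.
#'
#' @param trial_betas result of \code{\link{estimate_trial_betas}}.
#' @return Matrix voxels-by-tasks of t values.
#' @export
roi_tmap <- function(trial_betas) {
  tasks <- unique(trial_betas$trials$task1)
  out <- sapply(tasks, function(task) {
    B <- trial_betas$betas[trial_betas$trials$task1 == task, , drop = FALSE]
    m <- colMeans(B)
    s <- apply(B, 2, stats::sd)
    m / (s / sqrt(nrow(B)))
  })
  matrix(out, ncol = length(tasks), dimnames = list(NULL, tasks))
}

#' Select the most activated (or co-activated) voxels
#'
#' \code{mode = "single"}: the k voxels with the largest t values for one
#' task. \code{mode = "conjunction"}: the k voxels with the largest
#' minimum t across the two tasks (most co-activated). Ties break by
#' ascending voxel index, so selection is deterministic.
#'
#' @param tmaps voxels-by-tasks t matrix (\code{\link{roi_tmap}}).
#' @param k number of voxels (default 50).
#' @param mode \code{"single"} or \code{"conjunction"}.
#' @param task column to use in single mode (default first).
#' @return Integer vector of k voxel indices (unsorted by index; ranked by
#'   criterion).
#' @export
select_features <- function(tmaps, k = 50,
                            mode = c("single", "conjunction"),
                            task = NULL) {
  mode <- match.arg(mode)
  tmaps <- as.matrix(tmaps)
  if (k > nrow(tmaps))
    stop("k exceeds the number of voxels (", nrow(tmaps), ")")
  crit <- if (mode == "single") {
    col <- if (is.null(task)) 1 else task
    tmaps[, col]
  } else {
    if (ncol(tmaps) < 2) stop("conjunction mode needs two task t-maps")
    do.call(pmin, lapply(seq_len(ncol(tmaps)), function(j) tmaps[, j]))
  }
  order(-crit, seq_along(crit))[seq_len(k)]
}

# L2-penalized logistic regression by Newton iteration; intercept
# unpenalized; deterministic. Objective: sum log-loss + (lambda/2)||w||^2.
ridge_logistic <- function(X, y, lambda, maxit = 100, tol = 1e-10) {
  p <- ncol(X)
  Xa <- cbind(1, X)
  beta <- numeric(p + 1)
  pen <- c(0, rep(lambda, p))
  for (it in seq_len(maxit)) {
    eta <- drop(Xa %*% beta)
    mu <- 1 / (1 + exp(-eta))
    g <- drop(crossprod(Xa, mu - y)) + pen * beta
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Xa * w, Xa)
    diag(H) <- diag(H) + pen
    step <- solve(H, g)
    beta <- beta - step
    if (max(abs(g)) < tol) break
  }
  beta
}

#' Train an 8-way one-vs-rest pattern classifier
#'
#' Eight binary L2-regularized logistic regressions (one stimulus-response
#' mapping against the other seven) sharing the penalty (default 25, on
#' the summed log-loss with the intercept unpenalized). Features are
#' z-scored with training-set statistics, which are stored and reapplied
#' at test time. Deterministic given the data.
#'
#' @param patterns trials-by-features matrix.
#' @param labels mapping labels (1..n_classes) per trial.
#' @param penalty L2 regularization strength.
#' @param n_classes number of mappings (default 8).
#' @return Object of class \code{"pattern_classifier"}: weight matrix
#'   \code{W} (features-by-classes), intercepts \code{b}, scaling
#'   \code{center}/\code{scale}, \code{penalty}, \code{classes}.
#' @export
train_classifier <- function(patterns, labels, penalty = 25,
                             n_classes = 8) {
  patterns <- as.matrix(patterns)
  labels <- as.integer(labels)
  classes <- seq_len(n_classes)
  missing <- setdiff(classes, unique(labels))
  if (length(missing))
    stop("no training trials for mapping(s): ",
         paste(missing, collapse = ", "))
  tab <- table(factor(labels, classes))
  if (any(tab < 2))
    warning("fewer than 2 training trials for mapping(s): ",
            paste(classes[tab < 2], collapse = ", "))
  ctr <- colMeans(patterns)
  scl <- apply(patterns, 2, stats::sd)
  scl[scl == 0] <- 1
  Z <- scale(patterns, ctr, scl)
  coefs <- sapply(classes, function(m)
    ridge_logistic(Z, as.numeric(labels == m), penalty))
  structure(list(W = coefs[-1, , drop = FALSE], b = coefs[1, ],
                 center = ctr, scale = scl, penalty = penalty,
                 classes = classes),
            class = "pattern_classifier")
}

# one-vs-rest decision values (trials-by-classes)
decision_values <- function(clf, patterns) {
  Z <- scale(as.matrix(patterns), clf$center, clf$scale)
  sweep(Z %*% clf$W, 2, clf$b, "+")
}

#' Predict mapping labels
#'
#' Argmax over the one-vs-rest decision values; exact ties break to the
#' lowest label index.
#'
#' @param clf a \code{\link{train_classifier}} result.
#' @param patterns trials-by-features matrix (single pattern vectors are
#'   accepted).
#' @return Integer label(s).
#' @export
predict_label <- function(clf, patterns) {
  if (is.null(dim(patterns))) patterns <- matrix(patterns, 1)
  if (ncol(patterns) != nrow(clf$W))
    stop("pattern dimension ", ncol(patterns),
         " does not match classifier features ", nrow(clf$W))
  bad <- !stats::complete.cases(patterns)
  dv <- decision_values(clf, patterns)
  dv[bad, ] <- 0
  pred <- apply(dv, 1, which.max)  # which.max: lowest index on ties
  pred[bad] <- NA_integer_
  pred
}

#' Leave-one-run-out cross-validated decoding accuracy
#'
#' @param patterns trials-by-features matrix.
#' @param labels mapping labels.
#' @param run_ids fold (run) id per trial.
#' @param penalty L2 strength.
#' @param n_classes number of mappings.
#' @return List: pooled \code{accuracy} (proportion of all test trials
#'   correct), \code{folds} data.frame (run, n, correct).
#' @export
cv_decode <- function(patterns, labels, run_ids, penalty = 25,
                      n_classes = 8) {
  runs <- unique(run_ids)
  if (length(runs) < 2) stop("need at least 2 runs for cross-validation")
  folds <- lapply(runs, function(r) {
    test <- which(run_ids == r)
    if (!length(test)) {
      warning("fold ", r, " has no test trials; skipped")
      return(NULL)
    }
    clf <- tryCatch(
      train_classifier(patterns[-test, , drop = FALSE],
                       labels[-test], penalty, n_classes),
      error = function(e) {
        warning("fold ", r, " skipped: ", conditionMessage(e))
        NULL
      })
    if (is.null(clf)) return(NULL)
    pred <- predict_label(clf, patterns[test, , drop = FALSE])
    data.frame(run = r, n = length(test),
               correct = sum(pred == labels[test]))
  })
  folds <- do.call(rbind, folds)
  list(accuracy = sum(folds$correct) / sum(folds$n), folds = folds)
}

#' Apply a trained classifier to another task's trials
#'
#' The cross-task specificity test: a classifier trained on one task is
#' tested on the other (control) task's patterns in the same feature
#' space; in modality-specific regions accuracy should sit at chance.
#'
#' @param clf a trained \code{\link{train_classifier}}.
#' @param patterns trials-by-features matrix from the other task.
#' @param labels that task's mapping labels.
#' @return Proportion correct.
#' @export
cross_decode <- function(clf, patterns, labels) {
  mean(predict_label(clf, patterns) == labels)
}

# mapping label of `task` within a trial row set (NA if task absent)
task_labels <- function(trials, task) {
  ifelse(trials$task1 == task, trials$map1,
         ifelse(!is.na(trials$task2) & trials$task2 == task,
                trials$map2, NA_integer_))
}

#' Time-resolved decoding of trial-wise timecourses
#'
#' Tests task-specific classifiers at every time point of the trial-wise
#' least-squares-sum timecourses, giving a decoding-accuracy timecourse.
#' When the tested condition is the training (single-task) condition, a
#' leave-one-run-out pairing keeps training and test independent; for
#' dual-task conditions the single-task training set is independent by
#' design and a single classifier is trained on all of it.
#'
#' @param train a \code{\link{estimate_trial_betas}} result (training
#'   patterns; single-task trials).
#' @param lss one condition's entry from
#'   \code{\link{estimate_trialwise_timecourses_lss}}.
#' @param task decoded task (\code{"AO"} or \code{"VM"}).
#' @param feature_idx voxel indices to use (default: all columns).
#' @param penalty L2 strength.
#' @param n_classes mappings per task.
#' @return Object of class \code{"decoding_timecourse"}: \code{time},
#'   \code{accuracy} per time point, \code{n_trials}, \code{decoder_task},
#'   \code{condition}.
#' @export
time_resolved_decode <- function(train, lss, task, feature_idx = NULL,
                                 penalty = 25, n_classes = 8) {
  tri <- train$trials
  sel <- which(tri$task1 == task)
  if (is.null(feature_idx)) feature_idx <- seq_len(ncol(train$betas))
  Xtr <- train$betas[sel, feature_idx, drop = FALSE]
  ytr <- tri$map1[sel]
  rtr <- tri$run[sel]
  yte <- task_labels(lss$trials, task)
  te <- which(!is.na(yte))
  if (!length(te)) stop("no test trials engage task ", task)
  nlag <- length(lss$time)
  correct <- matrix(NA, nlag, length(te))
  same_cond <- lss$condition %in% unique(tri$condition)
  if (same_cond) {
    for (r in unique(rtr)) {
      tr_idx <- rtr != r
      te_idx <- which(lss$trials$run[te] == r)
      if (!length(te_idx)) next
      clf <- tryCatch(
        train_classifier(Xtr[tr_idx, , drop = FALSE], ytr[tr_idx],
                         penalty, n_classes),
        error = function(e) {
          warning("fold ", r, " skipped: ", conditionMessage(e))
          NULL
        })
      if (is.null(clf)) next
      for (l in seq_len(nlag)) {
        P <- t(matrix(lss$betas[l, feature_idx, te[te_idx]],
                      nrow = length(feature_idx)))
        correct[l, te_idx] <- predict_label(clf, P) == yte[te[te_idx]]
      }
    }
  } else {
    clf <- train_classifier(Xtr, ytr, penalty, n_classes)
    for (l in seq_len(nlag)) {
      P <- t(matrix(lss$betas[l, feature_idx, te],
                    nrow = length(feature_idx)))
      correct[l, ] <- predict_label(clf, P) == yte[te]
    }
  }
  structure(list(time = lss$time,
                 accuracy = rowMeans(correct, na.rm = TRUE),
                 n_trials = length(te), decoder_task = task,
                 condition = lss$condition),
            class = "decoding_timecourse")
}

#' Pool task order for dual-task decoding timecourses
#'
#' Pointwise (unweighted) mean of two decoding timecourses on the same
#' time grid — e.g., the Task-2 curve at short SOA is the mean of the
#' AO-decoded VMAO and VM-decoded AOVM curves; trial counts sum.
#'
#' @param tc1,tc2 \code{decoding_timecourse} objects on identical grids.
#' @return Pooled \code{decoding_timecourse}.
#' @export
pool_task_order <- function(tc1, tc2) {
  if (length(tc1$time) != length(tc2$time) ||
      max(abs(tc1$time - tc2$time)) > 1e-9)
    stop("time grids differ; cannot pool")
  structure(list(time = tc1$time,
                 accuracy = rowMeans(cbind(tc1$accuracy, tc2$accuracy),
                                     na.rm = TRUE),
                 n_trials = tc1$n_trials + tc2$n_trials,
                 decoder_task = paste(unique(c(tc1$decoder_task,
                                               tc2$decoder_task)),
                                      collapse = "+"),
                 condition = paste(tc1$condition, tc2$condition,
                                   sep = "+")),
            class = "decoding_timecourse")
}

#' Latency metrics of a decoding-accuracy timecourse
#'
#' Fits the single-gamma curve above the chance baseline and extracts
#' onset/peak latency, amplitude and FWHM.
#'
#' @param tc a \code{decoding_timecourse}.
#' @param baseline chance rate (default 1/8).
#' @param ... passed to \code{\link{latency_metrics}}.
#' @return List: \code{curve} (the fit) and the latency metrics.
#' @export
decode_latency <- function(tc, baseline = 1 / 8, ...) {
  ok <- is.finite(tc$accuracy)
  curve <- fit_single_gamma(tc$time[ok], tc$accuracy[ok], baseline)
  c(list(curve = curve), latency_metrics(curve, ...))
}
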