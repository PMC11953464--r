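test_that("feature selection matches a brute-force ranking oracle", {
  set.seed(30)
  tm <- cbind(AO = rnorm(120), VM = rnorm(120))
  fi <- select_features(tm, 50, "single", task = "AO")
  expect_length(fi, 50)
  expect_identical(fi, order(-tm[, "AO"], seq_len(120))[1:50])
  fc <- select_features(tm, 50, "conjunction")
  expect_identical(fc, order(-pmin(tm[, 1], tm[, 2]), seq_len(120))[1:50])
  # identity set when k = n
  expect_setequal(select_features(tm, 120, "single"), 1:120)
  expect_error(select_features(tm, 121), "exceeds")
  # a voxel maximal in one task but at zero in the other drops out of the
  # conjunction set when its min-rank is too low
  tm2 <- cbind(AO = c(10, rep(1, 9)), VM = c(0, rep(1, 9)))
  expect_false(1 %in% select_features(tm2, 5, "conjunction"))
  expect_true(1 %in% select_features(tm2, 5, "single", task = "AO"))
})

test_that("the one-vs-rest ridge classifier separates separable patterns
           and matches glmnet on the shared objective", {
  set.seed(31)
  sp <- separable_patterns(n_per_class = 6)
  clf <- train_classifier(sp$X, sp$labels, penalty = 25)
  expect_equal(dim(clf$W), c(16, 8))
  expect_equal(mean(predict_label(clf, sp$X) == sp$labels), 1)
  # decision rule equals exhaustive comparison over the 8 sub-models
  Z <- scale(sp$X, clf$center, clf$scale)
  dv <- sweep(Z %*% clf$W, 2, clf$b, "+")
  expect_equal(predict_label(clf, sp$X), apply(dv, 1, which.max))
  # deterministic on a zero pattern
  z1 <- predict_label(clf, rep(0, 16))
  expect_identical(z1, predict_label(clf, rep(0, 16)))
  # large penalty shrinks weights toward zero
  clf_big <- train_classifier(sp$X, sp$labels, penalty = 1e7)
  expect_lt(max(abs(clf_big$W)), 1e-3)
  expect_error(train_classifier(sp$X[sp$labels != 3, ],
                                sp$labels[sp$labels != 3]),
               "3")
  expect_error(predict_label(clf, rep(0, 5)), "dimension")
})

test_that("ridge logistic agrees with glmnet's penalized fit", {
  skip_if_not_installed("glmnet")
  set.seed(32)
  n <- 60; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  y <- as.numeric(runif(n) < plogis(X[, 1] - 0.5 * X[, 2]))
  lambda <- 5
  mine <- serialq:::ridge_logistic(X, y, lambda)
  g <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                      lambda = lambda / n, standardize = FALSE,
                      thresh = 1e-14)
  ref <- c(g$a0, as.numeric(g$beta))
  expect_equal(mine, ref, tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("cross-validated decoding is perfect for separable patterns,
           at chance for shuffled labels, and pools folds correctly", {
  set.seed(33)
  sp <- separable_patterns(n_per_class = 10)
  cv <- cv_decode(sp$X, sp$labels, sp$runs)
  expect_equal(cv$accuracy, 1)
  expect_equal(cv$accuracy,
               sum(cv$folds$correct) / sum(cv$folds$n))  # recount
  # pure-noise patterns decode at chance when label permutations respect
  # the run structure (each run keeps one trial per mapping, so training
  # and test class frequencies stay balanced)
  labels <- rep(1:8, each = 10)
  runs <- rep_len(1:10, 80)
  accs <- replicate(20, {
    y <- labels
    for (r in unique(runs)) {
      i <- which(runs == r)
      y[i] <- sample(y[i])
    }
    Xn <- matrix(rnorm(80 * 16), 80, 16)
    suppressWarnings(cv_decode(Xn, y, runs)$accuracy)
  })
  n_tot <- 20 * 80
  expect_lt(abs(mean(accs) - 0.125),
            4 * sqrt(0.125 * 0.875 / n_tot) + 0.01)
})

test_that("cross-task tests sit at chance when the other task evokes no
           pattern", {
  set.seed(34)
  sp <- separable_patterns(n_per_class = 10)
  clf <- train_classifier(sp$X, sp$labels)
  other <- matrix(rnorm(80 * 16, 0, 0.5), 80, 16)  # patternless trials
  acc <- cross_decode(clf, other, rep_len(1:8, 80))
  expect_lt(abs(acc - 0.125), 0.12)
  expect_gt(cross_decode(clf, sp$X, sp$labels), 0.9)
})

test_that("time-resolved decoding localizes a pattern injected in a
           known lag window", {
  set.seed(35)
  n_tr <- 48; k <- 16; nlag <- 30
  labels <- rep_len(1:8, n_tr)
  runs <- rep(1:4, each = 12)
  proto <- diag(8)[, rep(1:8, length.out = k)] * 0  # build prototypes
  proto <- matrix(0, 8, k); for (m in 1:8) proto[m, m] <- 1
  train <- list(betas = proto[labels, ] + matrix(rnorm(n_tr * k, 0, .1),
                                                 n_tr, k),
                trials = data.frame(run = runs, trial = 1:n_tr,
                                    condition = "AO", task1 = "AO",
                                    map1 = labels, rt1 = 1))
  arr <- array(rnorm(nlag * k * n_tr, 0, 1), c(nlag, k, n_tr))
  active <- 10:18
  for (i in seq_len(n_tr))
    for (l in active)
      arr[l, , i] <- arr[l, , i] + 4 * proto[labels[i], ]
  lss <- list(condition = "AO", time = (0:(nlag - 1)) * 0.199,
              trials = data.frame(run = runs, trial = 1:n_tr,
                                  condition = "AO", task1 = "AO",
                                  task2 = NA, soa = NA, map1 = labels,
                                  map2 = NA),
              betas = arr)
  tc <- time_resolved_decode(train, lss, "AO")
  expect_s3_class(tc, "decoding_timecourse")
  expect_gt(mean(tc$accuracy[active]), 0.75)
  expect_lt(mean(tc$accuracy[-(8:20)]), 0.3)
  # shuffling labels at every time point flattens the curve to chance
  lss_sh <- lss; lss_sh$trials$map1 <- sample(labels)
  tc_sh <- time_resolved_decode(train, lss_sh, "AO")
  expect_lt(abs(mean(tc_sh$accuracy) - 0.125),
            3 * sqrt(0.125 * 0.875 / (nlag * n_tr)) + 0.05)
})

test_that("task-order pooling averages pointwise and sums trials", {
  t1 <- structure(list(time = 0:4 * 0.199, accuracy = rep(0.125, 5),
                       n_trials = 10, decoder_task = "AO",
                       condition = "S-VMAO"),
                  class = "decoding_timecourse")
  t2 <- t1; t2$accuracy <- rep(0.25, 5); t2$decoder_task <- "VM"
  t2$condition <- "S-AOVM"; t2$n_trials <- 10
  p <- pool_task_order(t1, t2)
  expect_equal(p$accuracy, rep(0.1875, 5))
  expect_equal(p$n_trials, 20)
  expect_identical(pool_task_order(t1, t1)$accuracy, t1$accuracy)
  t3 <- t2; t3$time <- t3$time + 1
  expect_error(pool_task_order(t1, t3), "grid")
  # equal trial counts: pooled curve equals the union recount
  acc_union <- (t1$accuracy * 10 + t2$accuracy * 10) / 20
  expect_equal(p$accuracy, acc_union)
})
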