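## LOO logistic prediction, confusion metrics, ROC-AUC, bootstrap CIs.

test_that("perfectly separated 1-D data gives LOO accuracy 1", {
  set.seed(1)
  x <- matrix(c(rnorm(20, -10, 0.5), rnorm(20, 10, 0.5)), ncol = 1)
  y <- rep(c(0, 1), each = 20)
  p <- looLogistic(x, y, ridge = 1e-4)
  expect_equal(as.integer(p > 0.5), y)
})

test_that("ridge = 0 under perfect separation fails with advice", {
  x <- matrix(c(rep(-1, 5), rep(1, 5)), ncol = 1)
  y <- rep(c(0, 1), each = 5)
  expect_error(looLogistic(x, y, ridge = 0), "ridge")
})

test_that("a constant feature predicts the training-fold prior", {
  x <- matrix(1, nrow = 12, ncol = 1)
  y <- rep(c(0, 1), each = 6)
  p <- looLogistic(x, y)
  # leaving out a class-1 patient leaves 5/11 positives in the fold
  expect_equal(p[y == 1], rep(5 / 11, 6), tolerance = 1e-6)
  expect_equal(p[y == 0], rep(6 / 11, 6), tolerance = 1e-6)
})

test_that("permuted labels give chance-level AUC", {
  set.seed(77)
  W <- matrix(rnorm(240 * 3), ncol = 3)
  y <- sample(rep(c(0, 1), each = 120))
  p <- looLogistic(W, y)
  auc <- rocAUC(p, y)
  expect_gt(auc, 0.40)
  expect_lt(auc, 0.60)
})

test_that("confusion metrics honour the threshold and complementarity", {
  # 3 MPMS flagged, 1 missed; all 4 R correct
  prob <- c(0.1, 0.2, 0.3, 0.8, 0.9, 0.9, 0.7, 0.6)
  y    <- c(0,   0,   0,   0,   1,   1,   1,   1)
  cm <- confusionMetrics(prob, y, threshold = 0.5)
  expect_equal(cm$sensitivity_mpms, 0.75)
  expect_equal(cm$specificity_mpms, 1)
  expect_equal(cm$sensitivity_rtt, cm$specificity_mpms)
  expect_equal(cm$specificity_rtt, cm$sensitivity_mpms)
  # threshold 0: everything (with positive score) is called R
  cm0 <- confusionMetrics(prob, y, threshold = 0)
  expect_equal(cm0$sensitivity_rtt, 1)
  expect_equal(cm0$specificity_rtt, 0)
  expect_error(confusionMetrics(prob, rep(1, 8)), "both classes")
})

test_that("rocAUC equals the exhaustive pairwise-concordance oracle", {
  # fixed 6-point set with a tie across classes
  s <- c(0.1, 0.4, 0.4, 0.6, 0.8, 0.9)
  y <- c(0, 0, 1, 0, 1, 1)
  expect_equal(rocAUC(s, y), aucOracle(s, y))
  expect_equal(rocAUC(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(rocAUC(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(4:50, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- round(runif(n), 2)       # rounding forces occasional ties
    expect_equal(rocAUC(s, y), aucOracle(s, y), tolerance = 1e-12)
  }
})

test_that("rocAUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(6)
  y <- rep(c(0, 1), each = 25)
  s <- rnorm(50) + y
  expect_equal(rocAUC(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("stratified bootstrap CIs bracket the point estimate and are
          reproducible", {
  set.seed(9)
  y <- rep(c(0, 1), each = 40)
  p <- plogis(rnorm(80) + 1.5 * y)
  ci1 <- bootstrapCI(p, y, nBoot = 300, seed = 42)
  ci2 <- bootstrapCI(p, y, nBoot = 300, seed = 42)
  expect_identical(ci1, ci2)
  expect_true(all(ci1$lower <= ci1$value + 1e-12))
  expect_true(all(ci1$upper >= ci1$value - 1e-12))
  # degenerate case: perfect separation, zero-width CI at 1
  pd <- c(rep(0.1, 10), rep(0.9, 10))
  yd <- rep(c(0, 1), each = 10)
  cid <- bootstrapCI(pd, yd, metrics = "auc", nBoot = 100, seed = 1)
  expect_equal(cid$value, 1)
  expect_equal(cid$lower, 1)
  expect_equal(cid$upper, 1)
})

test_that("CI bracketing holds across many seeds (property run)", {
  set.seed(10)
  for (rep in 1:30) {
    y <- rep(c(0, 1), each = 30)
    p <- plogis(rnorm(60) + runif(1, 0, 2) * y)
    ci <- bootstrapCI(p, y, metrics = "auc", nBoot = 200, seed = rep)
    expect_true(ci$lower <= ci$value + 1e-12 && ci$upper >= ci$value - 1e-12)
  }
})

test_that("predictOutcome assembles a valid result object", {
  set.seed(11)
  W <- rbind(matrix(rnorm(60, -1), ncol = 2), matrix(rnorm(60, 1), ncol = 2))
  y <- rep(c(0, 1), each = 30)
  pr <- predictOutcome(W, y, nBoot = 200, seed = 3, modelName = "demo")
  expect_s4_class(pr, "PredictionResult")
  m <- predictionMetrics(pr)
  expect_setequal(m$metric, c("sensitivity_mpms", "specificity_mpms",
                              "sensitivity_rtt", "specificity_rtt", "auc"))
  expect_true(all(m$value >= 0 & m$value <= 1))
  expect_identical(pr@predicted, as.integer(pr@probabilities > 0.5))
})

test_that("increasing the class separation never hurts the AUC (pipeline
          monotonicity on scores)", {
  set.seed(12)
  shifts <- c(0, 0.5, 1, 2)
  med <- vapply(shifts, function(d) {
    aucs <- vapply(1:5, function(r) {
      set.seed(1000 + r)
      W <- matrix(rnorm(120), ncol = 1)
      y <- rep(c(0, 1), each = 60)
      W[y == 1, 1] <- W[y == 1, 1] + d
      rocAUC(looLogistic(W, y), y)
    }, numeric(1))
    median(aucs)
  }, numeric(1))
  expect_true(all(diff(med) >= -1e-9))
})
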