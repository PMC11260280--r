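## Morphology-based outcome prediction: ridge-penalized logistic
## regression on PC weights in a leave-one-out cross-validation, with
## sensitivity/specificity for both classes, ROC-AUC, and stratified
## bootstrap percentile confidence intervals.

# ridge-penalized logistic fit by iteratively reweighted least squares.
# X: n x p (already standardized), y: 0/1. The penalty applies to the
# coefficients, not the intercept. Returns c(intercept, beta).
.ridgeLogistic <- function(X, y, ridge, maxIters = 100, tol = 1e-10) {
  n <- nrow(X); p <- ncol(X)
  Xi <- cbind(1, X)
  beta <- numeric(p + 1L)
  pen <- diag(c(0, rep(ridge, p)), p + 1L)
  singular <- FALSE
  for (it in seq_len(maxIters)) {
    eta <- as.numeric(Xi %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    grad <- as.numeric(crossprod(Xi, y - mu)) - pen %*% beta
    H <- crossprod(Xi * w, Xi) + pen
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) { singular <- TRUE; break }
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < tol) return(beta)
  }
  # no convergence: with separable classes and no penalty there is no
  # finite maximum-likelihood estimate
  if (ridge <= 0)
    stop("logistic fit did not converge (perfect separation has no finite ",
         "estimate); use ridge > 0")
  if (singular || max(abs(beta)) > 1e8)
    stop("logistic fit diverged; increase the ridge penalty")
  beta
}

# standardize training columns; zero-variance columns are dropped
# (coefficient forced to 0) so a constant feature reduces to the prior
.standardize <- function(Xtr, Xte) {
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2L, sd)
  keep <- sdv > 0
  sdv[!keep] <- 1
  ztr <- sweep(sweep(Xtr, 2L, mu), 2L, sdv, "/")
  zte <- sweep(sweep(Xte, 2L, mu, check.margin = FALSE), 2L, sdv, "/")
  ztr[, !keep] <- 0
  zte[, !keep] <- 0
  list(train = ztr, test = zte)
}

#' Leave-one-out logistic prediction
#'
#' For each patient, a ridge-penalized logistic regression is fitted on
#' all other patients' PC weights and the held-out patient's probability
#' of class 1 (response to treatment) is recorded. Predictors are
#' standardized with training-fold statistics only, so no information
#' leaks from the held-out case. Deterministic given its inputs.
#'
#' @param weights n x m matrix of PC weights (patients x modes).
#' @param labels 0/1 outcome vector (1 = R, 0 = MPMS).
#' @param nModes number of leading modes used as predictors.
#' @param ridge ridge penalty on standardized coefficients; the small
#'   default guarantees a finite fit even under perfect separation.
#' @return numeric vector of held-out probabilities of class 1.
#' @export
looLogistic <- function(weights, labels, nModes = ncol(weights),
                        ridge = 1e-4) {
  weights <- as.matrix(weights)
  labels <- as.integer(labels)
  if (nModes > ncol(weights)) stop("nModes exceeds the available modes")
  if (sum(labels == 1L) < 2L || sum(labels == 0L) < 2L)
    stop("need at least 2 patients per class")
  X <- weights[, seq_len(nModes), drop = FALSE]
  n <- nrow(X)
  probs <- numeric(n)
  for (i in seq_len(n)) {
    ytr <- labels[-i]
    if (length(unique(ytr)) < 2L)
      stop("training fold contains a single class")
    z <- .standardize(X[-i, , drop = FALSE], X[i, , drop = FALSE])
    beta <- .ridgeLogistic(z$train, ytr, ridge)
    probs[i] <- plogis(sum(c(1, z$test) * beta))
  }
  probs
}

#' Sensitivity and specificity for both target classes
#'
#' Labels predicted R (class 1) when the probability exceeds the
#' threshold. Because the classes are complementary,
#' sensitivity(MPMS) = specificity(RTT) and vice versa; both views are
#' reported, as both detection tasks are clinically meaningful.
#'
#' @param probabilities probability of class R per patient.
#' @param labels true 0/1 labels (1 = R); both classes must be present.
#' @param threshold classification threshold on P(R).
#' @return one-row data.frame with sensitivity/specificity for detecting
#'   MPMS and RTT, plus the confusion counts.
#' @export
confusionMetrics <- function(probabilities, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("labels must contain both classes")
  pred <- as.integer(probabilities > threshold)
  tpR <- sum(pred == 1L & labels == 1L)
  fnR <- sum(pred == 0L & labels == 1L)
  tpM <- sum(pred == 0L & labels == 0L)
  fnM <- sum(pred == 1L & labels == 0L)
  data.frame(
    sensitivity_mpms = tpM / (tpM + fnM),
    specificity_mpms = tpR / (tpR + fnR),
    sensitivity_rtt  = tpR / (tpR + fnR),
    specificity_rtt  = tpM / (tpM + fnM),
    tp_rtt = tpR, fn_rtt = fnR, tp_mpms = tpM, fn_mpms = fnM)
}

#' Area under the ROC curve
#'
#' Computed as the pairwise concordance probability: the chance that a
#' random class-1 patient receives a higher score than a random class-0
#' patient, ties counted one half (equivalent to the rank-sum statistic).
#'
#' @param probabilities scores (higher = more likely class 1).
#' @param labels 0/1 labels; both classes required.
#' @return AUC in `[0, 1]`.
#' @export
rocAUC <- function(probabilities, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("labels must contain both classes")
  r <- rank(probabilities)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#' @param probabilities scores.
#' @param labels 0/1 labels.
#' @return data.frame with `threshold`, `fpr`, `tpr`, suitable for
#'   plotting.
#' @export
rocCurve <- function(probabilities, labels) {
  labels <- as.integer(labels)
  th <- c(Inf, sort(unique(probabilities), decreasing = TRUE), -Inf)
  pts <- t(vapply(th, function(t) {
    pred <- probabilities > t
    c(fpr = sum(pred & labels == 0L) / sum(labels == 0L),
      tpr = sum(pred & labels == 1L) / sum(labels == 1L))
  }, numeric(2L)))
  data.frame(threshold = th, fpr = pts[, "fpr"], tpr = pts[, "tpr"])
}

.metricValue <- function(metric, probabilities, labels, threshold) {
  if (metric == "auc") return(rocAUC(probabilities, labels))
  cm <- confusionMetrics(probabilities, labels, threshold)
  cm[[metric]]
}

#' Stratified bootstrap percentile confidence intervals
#'
#' Resamples the per-patient (probability, label) pairs with replacement,
#' stratified by class so every resample contains both classes, and
#' returns percentile confidence intervals for the requested metrics.
#' Reproducible under a fixed seed.
#'
#' @param probabilities per-patient probabilities (e.g. from
#'   [looLogistic()]).
#' @param labels 0/1 labels.
#' @param metrics metric names among `sensitivity_mpms`,
#'   `specificity_mpms`, `sensitivity_rtt`, `specificity_rtt`, `auc`.
#' @param nBoot bootstrap iterations (1000 by default).
#' @param alpha two-sided miscoverage; 0.05 gives 95% intervals.
#' @param seed RNG seed.
#' @param threshold classification threshold for the confusion metrics.
#' @return data.frame with columns metric, value (full-sample point
#'   estimate), lower, upper.
#' @export
bootstrapCI <- function(probabilities, labels,
                        metrics = c("sensitivity_mpms", "specificity_mpms",
                                    "sensitivity_rtt", "specificity_rtt",
                                    "auc"),
                        nBoot = 1000, alpha = 0.05, seed = 1,
                        threshold = 0.5) {
  labels <- as.integer(labels)
  idx1 <- which(labels == 1L); idx0 <- which(labels == 0L)
  if (!length(idx1) || !length(idx0)) stop("labels must contain both classes")
  point <- vapply(metrics, .metricValue, numeric(1L),
                  probabilities = probabilities, labels = labels,
                  threshold = threshold)
  draws <- matrix(NA_real_, nBoot, length(metrics))
  oldSeed <- .Random.seed_save()
  on.exit(.Random.seed_restore(oldSeed))
  set.seed(seed)
  for (b in seq_len(nBoot)) {
    take <- c(sample(idx1, length(idx1), replace = TRUE),
              sample(idx0, length(idx0), replace = TRUE))
    draws[b, ] <- vapply(metrics, .metricValue, numeric(1L),
                         probabilities = probabilities[take],
                         labels = labels[take], threshold = threshold)
  }
  ci <- apply(draws, 2L, quantile, probs = c(alpha / 2, 1 - alpha / 2),
              names = FALSE)
  data.frame(metric = metrics, value = unname(point),
             lower = ci[1L, ], upper = ci[2L, ], row.names = NULL)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(seed) {
  if (!is.null(seed)) assign(".Random.seed", seed, envir = globalenv())
}

#' Full outcome-prediction evaluation
#'
#' Runs the leave-one-out logistic prediction, computes sensitivity and
#' specificity for both detection tasks plus ROC-AUC, and attaches
#' stratified bootstrap percentile confidence intervals.
#'
#' @param weights n x m PC-weight matrix.
#' @param labels 0/1 outcome (1 = R).
#' @param nModes predictor mode count (typically the model's 98% variance
#'   mode count).
#' @param ridge ridge penalty (see [looLogistic()]).
#' @param threshold classification threshold.
#' @param nBoot bootstrap iterations.
#' @param seed bootstrap seed.
#' @param modelName label for reporting.
#' @return A [PredictionResult-class].
#' @export
predictOutcome <- function(weights, labels, nModes = ncol(weights),
                           ridge = 1e-4, threshold = 0.5, nBoot = 1000,
                           seed = 1, modelName = "model") {
  labels <- as.integer(labels)
  probs <- looLogistic(weights, labels, nModes = nModes, ridge = ridge)
  metrics <- bootstrapCI(probs, labels, nBoot = nBoot, seed = seed,
                         threshold = threshold)
  new("PredictionResult", labels = labels, probabilities = probs,
      predicted = as.integer(probs > threshold), threshold = threshold,
      metrics = metrics, nBoot = as.integer(nBoot), seed = as.integer(seed),
      modelName = modelName)
}
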