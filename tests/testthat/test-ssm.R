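## Shape-model construction, projection, reconstruction, compactness,
## generalization, mode shapes.

octaShapes <- function(X) {
  m <- octaMesh(1)
  lapply(seq_len(nrow(X)), function(i)
    CorrespondedShape(matrix(X[i, ], ncol = 3, byrow = TRUE), meshFaces(m),
                      "octa", sprintf("s%d", i)))
}

test_that("identical training shapes give zero variance and the shape as
          mean", {
  base <- as.vector(t(meshVertices(octaMesh(3))))
  mod <- buildShapeModel(octaShapes(rbind(base, base, base)))
  expect_true(all(modelVariances(mod) < 1e-20))
  expect_equal(as.vector(t(modelMean(mod))), base)
})

test_that("a planted single mode is recovered with unit sample variance", {
  base <- as.vector(t(meshVertices(octaMesh(3))))
  set.seed(1)
  mdir <- rnorm(length(base)); mdir <- mdir / sqrt(sum(mdir^2))
  X <- rbind(base - mdir, base, base + mdir)
  mod <- buildShapeModel(octaShapes(X))
  v <- modelVariances(mod)
  expect_equal(v[1], 1, tolerance = 1e-9)          # n-1 divisor
  expect_true(all(v[-1] < 1e-18))
  expect_equal(abs(sum(modelModes(mod)[, 1] * mdir)), 1, tolerance = 1e-9)
})

test_that("variances match an explicit covariance eigendecomposition", {
  set.seed(2)
  base <- as.vector(t(meshVertices(octaMesh(4))))
  X <- t(replicate(6, base + rnorm(length(base), sd = 0.5)))
  mod <- buildShapeModel(octaShapes(X))
  C <- cov(X)                       # brute-force covariance oracle
  ev <- eigen(C, symmetric = TRUE)$values
  k <- length(modelVariances(mod))
  expect_equal(modelVariances(mod), ev[seq_len(k)], tolerance = 1e-9)
})

test_that("projection weights behave like orthonormal coordinates", {
  set.seed(3)
  base <- as.vector(t(meshVertices(octaMesh(4))))
  X <- t(replicate(5, base + rnorm(length(base), sd = 0.4)))
  mod <- buildShapeModel(octaShapes(X))
  mu <- modelMean(mod)
  expect_equal(projectShape(mod, mu, align = FALSE),
               rep(0, numModes(mod)), tolerance = 1e-10)
  i <- 1; s <- sqrt(modelVariances(mod)[i])
  shifted <- matrix(as.vector(t(mu)) + 2 * s * modelModes(mod)[, i],
                    ncol = 3, byrow = TRUE)
  w <- projectShape(mod, shifted, align = FALSE)
  expect_equal(w[i], 2 * s, tolerance = 1e-9)
  expect_true(all(abs(w[-i]) < 1e-9))
})

test_that("projection is least-squares optimal against grid perturbation", {
  set.seed(4)
  base <- as.vector(t(meshVertices(octaMesh(4))))
  X <- t(replicate(5, base + rnorm(length(base), sd = 0.4)))
  mod <- buildShapeModel(octaShapes(X))
  test <- matrix(base + rnorm(length(base), sd = 0.6), ncol = 3, byrow = TRUE)
  k <- 2
  w <- projectShape(mod, test, nModes = k, align = FALSE)
  resid <- function(wv) {
    rec <- shapeCoords(reconstructShape(mod, wv, k))
    sum((rec - test)^2)
  }
  r0 <- resid(w)
  for (d in c(-0.05, 0.05)) for (j in 1:k) {
    wp <- w; wp[j] <- wp[j] + d
    expect_gte(resid(wp), r0)
  }
})

test_that("full-mode reconstruction reproduces training shapes; truncation
          error equals the discarded variance", {
  set.seed(5)
  base <- as.vector(t(meshVertices(octaMesh(4))))
  X <- t(replicate(6, base + rnorm(length(base), sd = 0.5)))
  shapes <- octaShapes(X)
  mod <- buildShapeModel(shapes)
  n <- nrow(X)
  for (s in shapes) {
    w <- projectShape(mod, s, align = FALSE)
    rec <- reconstructShape(mod, w)
    expect_lt(max(abs(shapeCoords(rec) - shapeCoords(s))), 1e-6)
  }
  # algebraic identity: mean squared reconstruction error over the training
  # set with k modes = sum of discarded variances * (n-1)/n
  for (k in c(1, 3)) {
    mse <- mean(vapply(shapes, function(s) {
      w <- projectShape(mod, s, nModes = k, align = FALSE)
      sum((shapeCoords(reconstructShape(mod, w, k)) - shapeCoords(s))^2)
    }, numeric(1)))
    expect_equal(mse, sum(modelVariances(mod)[-(1:k)]) * (n - 1) / n,
                 tolerance = 1e-9)
  }
})

test_that("compactness arithmetic and the 98% mode rule", {
  fakeModel <- function(vars) {
    V <- length(vars) + 2
    base <- as.vector(t(matrix(rnorm(V * 3), ncol = 3)))
    modes <- qr.Q(qr(matrix(rnorm(3 * V * length(vars)), ncol = length(vars))))
    new("ShapeModel", templateId = "x", mean = base, modes = modes,
        variances = vars, nTrain = as.integer(length(vars) + 1),
        faces = matrix(integer(0), 0, 3))
  }
  set.seed(6)
  expect_equal(modelCompactness(fakeModel(c(4, 1)))$cumulative, c(0.8, 1))
  expect_equal(modesForVariance(fakeModel(c(0.90, 0.07, 0.02, 0.01)), 0.98), 3)
  expect_equal(modelCompactness(fakeModel(rep(2, 4)))$cumulative,
               c(0.25, 0.5, 0.75, 1))
  expect_error(modelCompactness(fakeModel(c(0, 0))), "zero")
})

test_that("leave-one-out generalization: planted subspace, hand oracle,
          monotonicity", {
  set.seed(7)
  base <- as.vector(t(meshVertices(octaMesh(4))))
  # planted modes orthogonal to rigid motions, tiny amplitude, so the
  # internal rigid alignment of the left-out shape is the identity to
  # within the asserted tolerance
  Vb <- matrix(base, ncol = 3, byrow = TRUE)
  Vc <- sweep(Vb, 2, colMeans(Vb))
  rigB <- cbind(rep(c(1, 0, 0), nrow(Vb)), rep(c(0, 1, 0), nrow(Vb)),
                rep(c(0, 0, 1), nrow(Vb)),
                as.vector(t(cbind(-Vc[, 2], Vc[, 1], 0))),
                as.vector(t(cbind(-Vc[, 3], 0, Vc[, 1]))),
                as.vector(t(cbind(0, -Vc[, 3], Vc[, 2]))))
  Q <- qr.Q(qr(cbind(rigB, matrix(rnorm(length(base) * 2), ncol = 2))))[, 7:8]
  # dataset exactly spanned by 2 planted modes
  A <- matrix(rnorm(20), ncol = 2)
  X <- t(apply(A, 1, function(a) base + as.numeric(Q %*% (c(2e-3, 1e-3) * a))))
  shapes <- octaShapes(X)
  gen <- generalizationLOO(shapes, maxModes = 4)
  expect_lt(gen$rmse[gen$modes == 2], 1e-6)
  expect_lt(gen$rmse[gen$modes == 4], 1e-6)
  expect_true(all(diff(gen$rmse) <= 1e-12))
  expect_equal(attr(gen, "repeats"), 10)

  # two identical shapes + one displaced by a small pose-free field:
  # hand-computed 0-mode errors are RMS(d)/2, RMS(d)/2 and RMS(d)
  s1 <- base
  delta <- rnorm(length(base))
  # make the displacement orthogonal to rigid motions so the internal
  # alignment is (to first order) the identity -- built here independently
  Vmat <- matrix(base, ncol = 3, byrow = TRUE)
  Vc <- sweep(Vmat, 2, colMeans(Vmat))
  rigBasis <- cbind(rep(c(1, 0, 0), nrow(Vmat)), rep(c(0, 1, 0), nrow(Vmat)),
                    rep(c(0, 0, 1), nrow(Vmat)),
                    as.vector(t(cbind(-Vc[, 2], Vc[, 1], 0))),
                    as.vector(t(cbind(-Vc[, 3], 0, Vc[, 1]))),
                    as.vector(t(cbind(0, -Vc[, 3], Vc[, 2]))))
  Qr <- qr.Q(qr(rigBasis))
  delta <- delta - Qr %*% crossprod(Qr, delta)
  delta <- 0.05 * delta / sqrt(sum(delta^2)) * sqrt(length(base) / 3)
  s3 <- base + as.numeric(delta)
  shapes3 <- octaShapes(rbind(s1, s1, s3))
  gen3 <- generalizationLOO(shapes3, maxModes = 1)
  r <- sqrt(mean(rowSums(matrix(delta, ncol = 3, byrow = TRUE)^2)))
  expect_equal(gen3$rmse[1], mean(c(r / 2, r / 2, r)), tolerance = 1e-3)
  expect_error(generalizationLOO(shapes3, maxModes = 2), "n - 2")
})

test_that("mode shapes sit at exact multiples of the mode SD", {
  set.seed(8)
  base <- as.vector(t(meshVertices(octaMesh(4))))
  X <- t(replicate(5, base + rnorm(length(base), sd = 0.5)))
  mod <- buildShapeModel(octaShapes(X))
  s <- sqrt(modelVariances(mod)[2])
  sh <- modeShapes(mod, 2, c(-2, 0, 2))
  expect_equal(shapeCoords(sh[["+0SD"]]), modelMean(mod))
  expect_equal((shapeCoords(sh[["+2SD"]]) + shapeCoords(sh[["-2SD"]])) / 2,
               modelMean(mod), tolerance = 1e-12)
  d <- as.vector(t(shapeCoords(sh[["+2SD"]]) - modelMean(mod)))
  expect_equal(sqrt(sum(d^2)), 2 * s, tolerance = 1e-9)
  expect_error(modeShapes(mod, 99), "invalid mode index")
})

test_that("mode signs are deterministic across rebuilds", {
  set.seed(9)
  base <- as.vector(t(meshVertices(octaMesh(4))))
  X <- t(replicate(6, base + rnorm(length(base), sd = 0.5)))
  m1 <- buildShapeModel(octaShapes(X))
  m2 <- buildShapeModel(octaShapes(X))
  expect_identical(modelModes(m1), modelModes(m2))
  for (j in seq_len(numModes(m1))) {
    col <- modelModes(m1)[, j]
    expect_gt(col[which.max(abs(col))], 0)
  }
})

test_that("PCA matches the explicit-covariance oracle over many random
          small datasets", {
  set.seed(10)
  for (rep in 1:25) {
    V <- sample(6:15, 1)
    n <- sample(3:8, 1)
    base <- rnorm(3 * V, sd = 5)
    X <- t(replicate(n, base + rnorm(3 * V, sd = runif(1, 0.1, 1))))
    m <- octaMesh(1)
    shapes <- lapply(seq_len(n), function(i)
      CorrespondedShape(matrix(X[i, ], ncol = 3, byrow = TRUE),
                        matrix(c(1L, 2L, 3L), 1), "t", sprintf("s%d", i)))
    mod <- buildShapeModel(shapes)
    ev <- eigen(cov(X), symmetric = TRUE)
    k <- length(modelVariances(mod))
    expect_equal(modelVariances(mod), ev$values[seq_len(k)],
                 tolerance = 1e-9)
    # principal angles for well-separated leading eigenvalues
    lead <- which(ev$values[1:k] > 1.5 * c(ev$values[2:k], 0))
    if (length(lead) > 0 && lead[1] == 1) {
      sv <- abs(sum(modelModes(mod)[, 1] * ev$vectors[, 1]))
      expect_lt(acos(pmin(sv, 1)), 1e-6)
    }
  }
})
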