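## Synthetic template and cohort generator.

test_that("templates are deterministic with documented counts and scale
          linearly in the size handle", {
  t1 <- makeTemplate("femur", resolution = 10, gaugeIters = 0)
  t2 <- makeTemplate("femur", resolution = 10, gaugeIters = 0)
  expect_identical(meshVertices(t1$mesh), meshVertices(t2$mesh))
  expect_identical(t1$fields, t2$fields)
  expect_equal(nrow(meshVertices(t1$mesh)), 100)
  expect_equal(nrow(meshFaces(t1$mesh)), 2 * 9 * 9)
  for (s in c(0.8, 1.3)) {
    ts <- makeTemplate("femur", resolution = 10, size = s, gaugeIters = 0)
    expect_equal(centroidSize(ts$mesh) / centroidSize(t1$mesh), s,
                 tolerance = 1e-9)
  }
  expect_error(makeTemplate("femur", resolution = 2), "resolution")
})

# sub-grid peak localisation along the central mediolateral profile
interLobeGap <- function(mesh, u, v) {
  vv <- meshVertices(mesh)
  mid <- abs(v - 0.5) < 0.03
  x <- vv[mid, 1]; z <- vv[mid, 3]
  o <- order(x); x <- x[o]; z <- z[o]
  peak <- function(side) {
    idx <- if (side < 0) which(x < 0) else which(x > 0)
    i <- idx[which.max(z[idx])]
    i <- min(max(i, 2), length(x) - 1)
    # quadratic interpolation around the discrete argmax
    a <- z[i - 1]; b <- z[i]; c <- z[i + 1]
    x[i] + 0.5 * (a - c) / (a - 2 * b + c + 1e-30) * (x[i + 1] - x[i])
  }
  peak(1) - peak(-1)
}

test_that("the notch handle strictly widens the measured inter-lobe gap", {
  res <- 48  # fine grid so the geometric probe resolves the peaks
  gaps <- vapply(c(0.7, 1, 1.3), function(no) {
    tpl <- makeTemplate("femur", resolution = res, notch = no, gaugeIters = 0)
    interLobeGap(tpl$mesh, tpl$u, tpl$v)
  }, numeric(1))
  expect_true(all(diff(gaps) > 0))
})

test_that("planted fields are orthonormal and the mask is sane", {
  tpl <- rawTemplate("femur", 10)
  g <- crossprod(tpl$fields)
  expect_lt(max(abs(g - diag(3))), 1e-10)
  expect_true(any(tpl$mask@include))
  expect_true(sum(!tpl$mask@include) > 0)
  expect_equal(length(tpl$mask@include), 100)
})

test_that("cohorts are reproducible under a fixed seed", {
  a <- generateCohort(cohortSpec(nR = 3, nMPMS = 3, resolution = 8, seed = 9, gaugeIters = 1))
  b <- generateCohort(cohortSpec(nR = 3, nMPMS = 3, resolution = 8, seed = 9, gaugeIters = 1))
  expect_identical(a$records, b$records)
  expect_identical(a$groundTruth, b$groundTruth)
  expect_identical(meshVertices(a$femur[[2]]), meshVertices(b$femur[[2]]))
  d <- generateCohort(cohortSpec(nR = 3, nMPMS = 3, resolution = 8, seed = 10, gaugeIters = 1))
  expect_false(identical(d$records$age, a$records$age))
})

test_that("generated records satisfy every record invariant, including the
          KOOS split by construction", {
  ch <- generateCohort(cohortSpec(nR = 15, nMPMS = 15, seed = 4,
                                  meshes = FALSE))
  rec <- ch$records
  expect_silent(validateRecords(rec))
  expect_true(all(rec$koos_pain[rec$group == "R"] > 75))
  expect_true(all(rec$koos_pain[rec$group == "MPMS"] <= 75))
  expect_equal(nrow(rec), 30)
  # cartilage counts are matched between groups by design
  for (v in c("cart_mfc", "cart_ltp")) {
    tr <- table(rec[[v]][rec$group == "R"])
    tm <- table(rec[[v]][rec$group == "MPMS"])
    expect_identical(tr, tm)
  }
})

test_that("planted group shifts appear in the ground-truth scores with the
          documented signs", {
  ch <- generateCohort(cohortSpec(nR = 200, nMPMS = 200, seed = 5,
                                  meshes = FALSE))
  gt <- ch$groundTruth
  dSize <- mean(gt$size[gt$group == "MPMS"]) - mean(gt$size[gt$group == "R"])
  dNotch <- mean(gt$notch[gt$group == "MPMS"]) - mean(gt$notch[gt$group == "R"])
  dCond <- mean(gt$condyle[gt$group == "MPMS"]) - mean(gt$condyle[gt$group == "R"])
  expect_lt(dSize, -0.5)    # MPMS smaller
  expect_gt(dNotch, 0.4)    # MPMS wider notch
  expect_lt(dCond, -0.3)    # MPMS narrower medial condyle
})

test_that("sex and the size score are strongly correlated", {
  ch <- generateCohort(cohortSpec(nR = 200, nMPMS = 200, seed = 6,
                                  meshes = FALSE))
  r <- cor(ch$records$sex, ch$groundTruth$size)
  expect_gt(r, 0.6)
})

test_that("zero-shift cohorts are null: Welch rejections near the nominal
          rate on ground-truth scores", {
  pvals <- unlist(lapply(1:60, function(s) {
    ch <- generateCohort(cohortSpec(nR = 40, nMPMS = 40, shiftSize = 0,
                                    shiftNotch = 0, shiftCondyle = 0,
                                    seed = s, meshes = FALSE))
    gt <- ch$groundTruth
    vapply(c("size", "notch", "condyle"), function(v)
      welchTest(gt[[v]][gt$group == "R"], gt[[v]][gt$group == "MPMS"])$p,
      numeric(1))
  }))
  rate <- mean(pvals < 0.05)
  # 180 draws: the 95% binomial band around the nominal 5% is about
  # [0.017, 0.089]
  expect_gt(rate, 0.015)
  expect_lt(rate, 0.095)
})

test_that("the power of the default size shift is high at full cohort size", {
  rej <- vapply(1:25, function(s) {
    ch <- generateCohort(cohortSpec(seed = s, meshes = FALSE))
    gt <- ch$groundTruth
    welchTest(gt$size[gt$group == "R"], gt$size[gt$group == "MPMS"])$p < 0.001
  }, logical(1))
  expect_gte(mean(rej), 0.99)
})

test_that("infeasible specs are rejected", {
  expect_error(cohortSpec(nR = 1), "at least 2")
  expect_error(cohortSpec(noiseSD = -1), "SDs")
  expect_error(cohortSpec(shiftSize = Inf), "finite")
})
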