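## Rigid GPA (no scaling), cropping, joint assembly.

mkShapes <- function(coords, n, posed = TRUE, faces, templateId = "tpl") {
  lapply(seq_len(n), function(i) {
    cc <- if (posed) applyRigid(coords, randomRigid()) else coords
    CorrespondedShape(cc, faces, templateId = templateId,
                      sourceId = sprintf("s%d", i))
  })
}

test_that("GPA exactly recovers shapes identical up to rigid transforms", {
  set.seed(5)
  m <- octaMesh(8)
  shapes <- mkShapes(meshVertices(m), 4, posed = TRUE, faces = meshFaces(m))
  al <- gpaRigid(shapes)
  ref <- shapeCoords(al@shapes[[1]])
  for (s in al@shapes[-1])
    expect_lt(max(abs(shapeCoords(s) - ref)), 1e-6)
})

test_that("GPA never scales: centroid sizes are preserved exactly", {
  set.seed(6)
  m <- octaMesh(8)
  big <- 2 * meshVertices(m)
  shapes <- c(mkShapes(meshVertices(m), 2, faces = meshFaces(m)),
              mkShapes(big, 1, faces = meshFaces(m)))
  sizesBefore <- vapply(shapes, centroidSize, numeric(1))
  al <- gpaRigid(shapes)
  sizesAfter <- vapply(al@shapes, centroidSize, numeric(1))
  expect_equal(sizesAfter, sizesBefore, tolerance = 1e-9)
  expect_equal(sizesAfter[3] / sizesAfter[1], 2, tolerance = 1e-9)
})

test_that("GPA reduces the summed squared corresponding-point distances", {
  set.seed(8)
  m <- octaMesh(8)
  # three genuinely different shapes in random poses
  shapes <- lapply(1:3, function(i) {
    cc <- meshVertices(m) + matrix(rnorm(18, sd = 0.3), ncol = 3)
    CorrespondedShape(applyRigid(cc, randomRigid()), meshFaces(m),
                      templateId = "tpl", sourceId = sprintf("s%d", i))
  })
  # independent accumulation of the pairwise Procrustes objective
  objective <- function(lst) {
    tot <- 0
    for (i in 1:2) for (j in (i + 1):3)
      tot <- tot + sum((shapeCoords(lst[[i]]) - shapeCoords(lst[[j]]))^2)
    tot
  }
  al <- gpaRigid(shapes)
  expect_lte(objective(al@shapes), objective(shapes))
})

test_that("GPA output is invariant to a common rigid transform of inputs", {
  set.seed(12)
  m <- octaMesh(8)
  shapes <- lapply(1:3, function(i) {
    cc <- meshVertices(m) + matrix(rnorm(18, sd = 0.2), ncol = 3)
    CorrespondedShape(cc, meshFaces(m), "tpl", sprintf("s%d", i))
  })
  al1 <- gpaRigid(shapes)
  tr <- randomRigid()
  shapes2 <- lapply(shapes, function(s)
    CorrespondedShape(applyRigid(shapeCoords(s), tr), meshFaces(m), "tpl",
                      s@sourceId))
  al2 <- gpaRigid(shapes2)
  for (i in 1:3)
    expect_lt(max(abs(shapeCoords(al2@shapes[[i]]) -
                        shapeCoords(al1@shapes[[i]]))), 1e-6)
  # stored transforms are proper rotations and the centroid invariant holds
  for (tr2 in al2@transforms) expect_equal(det(tr2$R), 1, tolerance = 1e-9)
})

test_that("cropping keeps coordinates, restricts faces, and commutes with
          rigid motion", {
  tpl <- rawTemplate("tibia", 8)
  shape <- CorrespondedShape(meshVertices(tpl$mesh), meshFaces(tpl$mesh),
                             tpl$mesh@name, "s1")
  allMask <- VertexMask(rep(TRUE, nrow(shapeCoords(shape))), tpl$mesh@name)
  expect_equal(shapeCoords(cropRegion(shape, allMask)), shapeCoords(shape))
  k <- 20
  mask <- VertexMask(seq_len(nrow(shapeCoords(shape))) <= k, tpl$mesh@name)
  cr <- cropRegion(shape, mask)
  expect_equal(nrow(shapeCoords(cr)), k)
  expect_equal(shapeCoords(cr), shapeCoords(shape)[1:k, ])
  f <- shapeCoords(shape)
  set.seed(2); tr <- randomRigid()
  moved <- CorrespondedShape(applyRigid(f, tr), meshFaces(tpl$mesh),
                             tpl$mesh@name, "s1")
  expect_equal(shapeCoords(cropRegion(moved, mask)),
               applyRigid(shapeCoords(cr), tr), tolerance = 1e-12)
  expect_error(cropRegion(shape, VertexMask(c(TRUE, FALSE), tpl$mesh@name)),
               "mask length")
})

test_that("joint assembly removes relative-pose variance entirely", {
  set.seed(33)
  fm <- octaMesh(10); tb <- octaMesh(6)
  n <- 5
  # identical bone geometry, random relative pose per patient
  fshapes <- mkShapes(meshVertices(fm), n, posed = TRUE, faces = meshFaces(fm),
                      templateId = "fem")
  tshapes <- mkShapes(meshVertices(tb), n, posed = TRUE, faces = meshFaces(tb),
                      templateId = "tib")
  alF <- gpaRigid(fshapes); alT <- gpaRigid(tshapes)
  joints <- assembleJoint(alF, alT)
  expect_equal(nrow(shapeCoords(joints[[1]])),
               nrow(meshVertices(fm)) + nrow(meshVertices(tb)))
  X <- do.call(rbind, lapply(joints, function(s) as.vector(t(shapeCoords(s)))))
  totalVar <- sum(apply(X, 2, var))
  expect_lt(totalVar, 1e-10)
})

test_that("joint assembly reports unmatched patients", {
  set.seed(34)
  fm <- octaMesh(10); tb <- octaMesh(6)
  alF <- gpaRigid(mkShapes(meshVertices(fm), 3, faces = meshFaces(fm),
                           templateId = "fem"))
  alT <- gpaRigid(mkShapes(meshVertices(tb), 3, faces = meshFaces(tb),
                           templateId = "tib"))
  pairing <- data.frame(femur = c("s1", "s2", "sX"), tibia = c("s1", "s2", "s3"))
  expect_error(assembleJoint(alF, alT, pairing), "unmatched")
})
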