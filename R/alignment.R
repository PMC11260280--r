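## Rigid co-alignment of corresponded shapes (generalized Procrustes
## analysis WITHOUT scaling), region cropping, and assembly of combined
## tibiofemoral shapes in a neutral relative pose.

# rotation mapping a centred point cloud onto its principal axes, with
# axis signs fixed by the sign of the coordinate skewness (falling back to
# the largest-magnitude coordinate) and det +1 enforced
.canonicalAxes <- function(coords) {
  cc <- sweep(coords, 2L, colMeans(coords))
  V <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)$vectors
  proj <- cc %*% V
  for (j in 1:3) {
    sk <- sum(proj[, j]^3)
    s <- if (abs(sk) > 1e-8) sign(sk) else sign(proj[which.max(abs(proj[, j])), j])
    V[, j] <- V[, j] * s
    proj[, j] <- proj[, j] * s
  }
  if (det(V) < 0) {
    # flip the axis whose skewness is weakest to restore a proper rotation
    sk <- abs(colSums(proj^3))
    j <- which.min(sk)
    V[, j] <- -V[, j]
  }
  V
}

.checkSameTemplate <- function(shapes) {
  if (length(shapes) < 2L) stop("need at least 2 shapes")
  V <- nrow(shapes[[1L]]@coordinates)
  tid <- shapes[[1L]]@templateId
  for (s in shapes) {
    if (nrow(s@coordinates) != V || s@templateId != tid)
      stop("all shapes must live on the same template")
  }
  invisible(TRUE)
}

#' Generalized Procrustes alignment without scaling
#'
#' Rigidly aligns corresponded shapes to a common frame by iterating
#' optimal rotation+translation superposition of every shape onto the
#' evolving mean shape until the mean stabilizes. No scaling is applied:
#' the centroid size of every shape is preserved exactly, so overall size
#' remains available to the shape model as a mode of variation. The
#' reference is initialized at the first shape, making the procedure
#' deterministic.
#'
#' @param shapes list of [CorrespondedShape-class] on a common template.
#' @param tol convergence tolerance on the RMS change of the mean shape
#'   (mm).
#' @param maxIters maximum alignment sweeps.
#' @return An [AlignedSet-class]: aligned shapes, the Procrustes mean,
#'   and the proper-rotation + translation transform applied to each
#'   input.
#' @export
gpaRigid <- function(shapes, tol = 1e-7, maxIters = 100) {
  .checkSameTemplate(shapes)
  n <- length(shapes)
  orig <- lapply(shapes, shapeCoords)
  cur <- orig
  ref <- cur[[1L]]
  ref <- sweep(ref, 2L, colMeans(ref))
  converged <- FALSE
  for (it in seq_len(maxIters)) {
    cur <- lapply(cur, function(x) applyRigid(x, rigidFit(x, ref)))
    m <- Reduce(`+`, cur) / n
    change <- sqrt(mean((m - ref)^2))
    ref <- m
    if (change < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop(sprintf("GPA did not converge in %d iterations (last mean change %.3g mm)",
                 maxIters, change))
  # put the average of the shape centroids exactly at the origin
  grand <- Reduce(`+`, lapply(cur, colMeans)) / n
  cur <- lapply(cur, function(x) sweep(x, 2L, grand))
  ref <- sweep(ref, 2L, grand)
  # canonical output frame: rotate everything so the mean shape sits on its
  # principal axes with a deterministic sign convention; the aligned set is
  # then invariant (not merely equivariant) under a common rigid transform
  # of the inputs
  Rc <- .canonicalAxes(ref)
  cur <- lapply(cur, function(x) x %*% Rc)
  ref <- ref %*% Rc
  transforms <- lapply(seq_len(n), function(i) rigidFit(orig[[i]], cur[[i]]))
  faces <- shapes[[1L]]@faces
  tid <- shapes[[1L]]@templateId
  aligned <- lapply(seq_len(n), function(i)
    CorrespondedShape(cur[[i]], faces, templateId = tid,
                      sourceId = shapes[[i]]@sourceId))
  new("AlignedSet", shapes = aligned,
      meanShape = CorrespondedShape(ref, faces, templateId = tid,
                                    sourceId = "mean"),
      transforms = transforms, templateId = tid)
}

#' Crop a corresponded shape to an analysis region
#'
#' Restricts a shape to the vertices included by the mask (e.g. dropping
#' the bone shaft, whose extent varies with the scan field of view).
#' Retained coordinates are unchanged; faces are kept only when all three
#' corners are included, and reindexed onto the reduced template.
#'
#' @param shape a [CorrespondedShape-class].
#' @param mask a [VertexMask-class] over the shape's template.
#' @return A [CorrespondedShape-class] on the reduced template (id
#'   suffixed with `":crop"`).
#' @export
cropRegion <- function(shape, mask) {
  validObject(mask)
  inc <- mask@include
  if (length(inc) != nrow(shape@coordinates))
    stop("mask length does not match the shape's template vertex count")
  newIdx <- cumsum(inc)
  f <- shape@faces
  keepF <- inc[f[, 1L]] & inc[f[, 2L]] & inc[f[, 3L]]
  newFaces <- matrix(newIdx[f[keepF, , drop = FALSE]], ncol = 3L)
  CorrespondedShape(shape@coordinates[inc, , drop = FALSE], newFaces,
                    templateId = paste0(shape@templateId, ":crop"),
                    sourceId = shape@sourceId)
}

#' Assemble combined tibiofemoral joint shapes in a neutral pose
#'
#' Concatenates each patient's independently aligned femur and tibia into
#' one joint shape. Because every bone was aligned to its own cohort mean
#' beforehand, all patients share the same (cohort-neutral) relative bone
#' pose by construction: any between-patient variation in relative pose --
#' flexion, varus/valgus, rotation induced by positioning in the scanner --
#' is removed and cannot leak into the joint shape model. A fixed offset
#' is added to all femora so the two bones do not overlap in renderings;
#' being identical across patients, it contributes no variance.
#'
#' @param femurSet,tibiaSet [AlignedSet-class] objects from [gpaRigid()].
#' @param pairing two-column data.frame (`femur`, `tibia`) of sourceIds
#'   pairing each patient's bones; by default bones are paired by position.
#' @param femurOffset length-3 translation applied to every femur (mm).
#' @return list of [CorrespondedShape-class] joint shapes (femur vertices
#'   first, then tibia).
#' @export
assembleJoint <- function(femurSet, tibiaSet, pairing = NULL,
                          femurOffset = c(0, 0, 60)) {
  fs <- femurSet@shapes; ts <- tibiaSet@shapes
  fid <- vapply(fs, function(s) s@sourceId, "")
  tid <- vapply(ts, function(s) s@sourceId, "")
  if (is.null(pairing)) {
    if (length(fs) != length(ts))
      stop("femur and tibia sets differ in size; provide an explicit pairing")
    pairing <- data.frame(femur = fid, tibia = tid)
  }
  mf <- match(pairing$femur, fid)
  mt <- match(pairing$tibia, tid)
  if (anyNA(mf) || anyNA(mt))
    stop("unmatched patient in pairing: ",
         paste(c(pairing$femur[is.na(mf)], pairing$tibia[is.na(mt)]),
               collapse = ", "))
  nvF <- nrow(fs[[1L]]@coordinates)
  faces <- rbind(fs[[1L]]@faces, ts[[1L]]@faces + nvF)
  jointId <- paste0(femurSet@templateId, "+", tibiaSet@templateId)
  lapply(seq_len(nrow(pairing)), function(i) {
    fcoord <- sweep(fs[[mf[i]]]@coordinates, 2L, femurOffset, "+")
    CorrespondedShape(rbind(fcoord, ts[[mt[i]]]@coordinates), faces,
                      templateId = jointId, sourceId = pairing$femur[i])
  })
}
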