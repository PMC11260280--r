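## Dense correspondence by template registration: a rigid iterative
## closest-point (ICP) stage followed by an elastic, locally-affine
## regularized non-rigid ICP. The template's connectivity is preserved, so
## the deformed template provides one 3D point per template vertex on the
## target surface -- a dense set of pseudo-landmarks with consistent
## anatomical meaning across specimens.

# candidate principal-axes initializations (proper rotations only)
.axisFlips <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))

.initRigid <- function(tv, target) {
  At <- principalAxes(target@vertices)
  As <- principalAxes(tv)
  if (det(At) < 0) At[, 3L] <- -At[, 3L]
  if (det(As) < 0) As[, 3L] <- -As[, 3L]
  ct <- colMeans(target@vertices)
  cs <- colMeans(tv)
  best <- NULL; bestD <- Inf
  for (s in .axisFlips) {
    R <- At %*% diag(s) %*% t(As)
    tr <- list(R = R, t = ct - as.numeric(R %*% cs))
    d <- mean(.cpp_closest_on_mesh(applyRigid(tv, tr), target@vertices,
                                   target@faces)$dist)
    if (d < bestD) { bestD <- d; best <- tr }
  }
  best
}

.rigidICP <- function(tv, target, params) {
  tr <- .initRigid(tv, target)
  cur <- applyRigid(tv, tr)
  lastRMS <- Inf
  iters <- 0L
  for (it in seq_len(params@rigidMaxIters)) {
    iters <- it
    cp <- .cpp_closest_on_mesh(cur, target@vertices, target@faces)
    keep <- cp$dist <= params@searchRadius
    if (!any(keep)) stop("registration failure: no correspondences within ",
                         "search radius after rigid initialization")
    step <- rigidFit(cur[keep, , drop = FALSE], cp$points[keep, , drop = FALSE])
    cur <- applyRigid(cur, step)
    tr <- list(R = step$R %*% tr$R, t = as.numeric(step$R %*% tr$t) + step$t)
    rms <- sqrt(mean(cp$dist[keep]^2))
    if (abs(lastRMS - rms) < params@convergenceTol) break
    lastRMS <- rms
  }
  cp <- .cpp_closest_on_mesh(cur, target@vertices, target@faces)
  if (mean(cp$dist) > params@searchRadius)
    stop("registration failure: surfaces do not overlap after rigid stage ",
         sprintf("(mean distance %.2f mm > search radius %.2f mm)",
                 mean(cp$dist), params@searchRadius))
  # similarity initialization for the elastic stage: pre-scale the template
  # to the target's apparent size so the elastic deformation is small and
  # size-independent. This only initializes the correspondence search; the
  # output coordinates lie on the target, so no size information is lost.
  keep <- cp$dist <= params@searchRadius
  A <- sweep(cur[keep, , drop = FALSE], 2L,
             colMeans(cur[keep, , drop = FALSE]))
  B <- sweep(cp$points[keep, , drop = FALSE], 2L,
             colMeans(cp$points[keep, , drop = FALSE]))
  rf <- rigidFit(cur[keep, , drop = FALSE], cp$points[keep, , drop = FALSE])
  s <- sum(B * (A %*% t(rf$R))) / sum(A^2)
  if (is.finite(s) && s > 0.5 && s < 2) {
    ctr <- colMeans(cur)
    cur <- sweep(s * sweep(cur, 2L, ctr), 2L, ctr, "+")
    for (it in 1:5) {
      cp2 <- .cpp_closest_on_mesh(cur, target@vertices, target@faces)
      k2 <- cp2$dist <= params@searchRadius
      if (!any(k2)) break
      step <- rigidFit(cur[k2, , drop = FALSE], cp2$points[k2, , drop = FALSE])
      cur <- applyRigid(cur, step)
    }
  }
  list(coords = cur, transform = tr, iterations = iters)
}

# boundary edges of an open mesh: edges referenced by exactly one face
.boundaryEdges <- function(faces) {
  e <- rbind(faces[, 1:2], faces[, 2:3], faces[, c(3L, 1L)])
  e <- t(apply(e, 1L, sort))
  key <- paste(e[, 1L], e[, 2L])
  e[key %in% names(which(table(key) == 1L)), , drop = FALSE]
}

# closest points on a polyline given as segment endpoint matrices A, B
.closestOnSegments <- function(P, A, B) {
  nP <- nrow(P); nS <- nrow(A)
  best <- rep(Inf, nP)
  out <- matrix(0, nP, 3L)
  AB <- B - A
  len2 <- pmax(rowSums(AB^2), 1e-30)
  for (s in seq_len(nS)) {
    t <- pmin(pmax((sweep(P, 2L, A[s, ]) %*% AB[s, ]) / len2[s], 0), 1)
    proj <- outer(as.numeric(t), AB[s, ]) + rep(A[s, ], each = nP)
    d <- rowSums((P - proj)^2)
    hit <- d < best
    best[hit] <- d[hit]
    out[hit, ] <- proj[hit, , drop = FALSE]
  }
  list(points = out, dist = sqrt(best))
}

# sparse matrices for the locally-affine elastic solve, built once per
# template: D maps the stacked per-vertex 4x3 affines X to deformed
# positions (row i = [v_i, 1]); MG penalizes affine differences across
# template edges.
.elasticOperators <- function(v0, faces) {
  V <- nrow(v0)
  ii <- rep(seq_len(V), each = 4L)
  jj <- as.vector(vapply(seq_len(V), function(i) 4L * (i - 1L) + 1:4,
                         integer(4L)))
  xx <- as.vector(t(cbind(v0, 1)))
  D <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(V, 4L * V))
  e <- rbind(faces[, 1:2], faces[, 2:3], faces[, c(3L, 1L)])
  e <- unique(t(apply(e, 1L, sort)))
  E <- nrow(e)
  ig <- rep(seq_len(4L * E), 2L)
  jg <- c(as.vector(vapply(seq_len(E), function(k) 4L * (e[k, 1L] - 1L) + 1:4,
                           integer(4L))),
          as.vector(vapply(seq_len(E), function(k) 4L * (e[k, 2L] - 1L) + 1:4,
                           integer(4L))))
  xg <- c(rep(1, 4L * E), rep(-1, 4L * E))
  MG <- Matrix::sparseMatrix(i = ig, j = jg, x = xg,
                             dims = c(4L * E, 4L * V))
  list(D = D, MG = MG, edges = e)
}

.elasticNICP <- function(v0, faces, target, params, trace = FALSE) {
  # the locally-affine stiffness acts on homogeneous-coordinate blocks and
  # is not invariant under translation of the frame; solving in a frame
  # centred on the template makes the stage exactly rigid-equivariant
  ctr <- colMeans(v0)
  v0 <- sweep(v0, 2L, ctr)
  target <- TriangleMesh(sweep(target@vertices, 2L, ctr), target@faces,
                         target@name)
  V <- nrow(v0)
  ops <- .elasticOperators(v0, faces)
  stiff1 <- Matrix::crossprod(ops$MG)
  stiff3 <- Matrix::bdiag(stiff1, stiff1, stiff1)
  tn <- faceNormals(target)
  # X starts at the identity affine for every vertex
  X <- do.call(rbind, rep(list(rbind(diag(3), 0)), V))
  cur <- v0
  cosLimit <- cos(params@normalLimitDeg * pi / 180)
  stepDist <- numeric(0)
  chol <- NULL  # CHOLMOD factor reused across iterations (constant pattern)
  # on cropped (open) surfaces the template boundary must track the target
  # boundary, otherwise in-surface motion (e.g. overall size) is invisible
  # to surface-distance matching in low-curvature regions
  bTpl <- unique(as.vector(.boundaryEdges(faces)))
  bTgtE <- .boundaryEdges(target@faces)
  useBoundary <- length(bTpl) > 0L && nrow(bTgtE) > 0L
  gamma <- rep(params@planeBlend, V)
  if (useBoundary) gamma[bTpl] <- 0  # boundary: full point constraint
  for (alpha in params@elasticSteps) {
    for (inner in seq_len(params@elasticInnerIters)) {
      prev <- cur
      cp <- .cpp_closest_on_mesh(cur, target@vertices, target@faces)
      w <- as.numeric(cp$dist <= params@searchRadius)
      vn <- vertexNormals(TriangleMesh(cur, faces))
      nh <- tn[cp$tri, , drop = FALSE]
      agree <- rowSums(vn * nh)
      w[agree < cosLimit] <- 0
      targetPts <- cp$points
      if (useBoundary) {
        bc <- .closestOnSegments(cur[bTpl, , drop = FALSE],
                                 target@vertices[bTgtE[, 1L], , drop = FALSE],
                                 target@vertices[bTgtE[, 2L], , drop = FALSE])
        targetPts[bTpl, ] <- bc$points
        w[bTpl] <- as.numeric(bc$dist <= params@searchRadius)
      }
      if (sum(w) < 4L)
        stop("registration failure: too few valid correspondences in ",
             "elastic stage (stiffness ", signif(alpha, 3), ")")
      # data term: per vertex, a blend of a full 3D pull to the match point
      # (weight 1 - gamma) and a point-to-plane residual constraining only
      # the surface-normal component (weight gamma); the latter leaves
      # tangential placement to the stiffness prior, so correspondence does
      # not slide along steep surface relief
      if (params@planeBlend == 0) {
        # pure point-to-point: the three coordinate blocks decouple and one
        # quarter-size SPD system with three right-hand sides suffices
        W2 <- Matrix::Diagonal(x = w^2)
        A <- Matrix::forceSymmetric(
          alpha^2 * stiff1 + Matrix::crossprod(ops$D, W2 %*% ops$D) +
            Matrix::Diagonal(n = 4L * V, x = 1e-8))
        b <- Matrix::crossprod(ops$D, W2 %*% targetPts)
        chol <- if (is.null(chol)) Matrix::Cholesky(A, LDL = FALSE, perm = TRUE)
                else Matrix::update(chol, A)
        X <- as.matrix(Matrix::solve(chol, b))
      } else {
        wp2 <- w^2 * (1 - gamma)
        wq2 <- w^2 * gamma
        Ap1 <- Matrix::crossprod(ops$D, Matrix::Diagonal(x = wp2) %*% ops$D)
        P <- cbind(Matrix::Diagonal(x = nh[, 1L]) %*% ops$D,
                   Matrix::Diagonal(x = nh[, 2L]) %*% ops$D,
                   Matrix::Diagonal(x = nh[, 3L]) %*% ops$D)
        q <- rowSums(nh * targetPts)
        A <- Matrix::forceSymmetric(
          alpha^2 * stiff3 + Matrix::bdiag(Ap1, Ap1, Ap1) +
            Matrix::crossprod(P, Matrix::Diagonal(x = wq2) %*% P) +
            Matrix::Diagonal(n = 12L * V, x = 1e-8))
        b <- c(as.numeric(Matrix::crossprod(ops$D, wp2 * targetPts[, 1L])),
               as.numeric(Matrix::crossprod(ops$D, wp2 * targetPts[, 2L])),
               as.numeric(Matrix::crossprod(ops$D, wp2 * targetPts[, 3L]))) +
          as.numeric(Matrix::crossprod(P, wq2 * q))
        chol <- if (is.null(chol)) Matrix::Cholesky(A, LDL = FALSE, perm = TRUE)
                else Matrix::update(chol, A)
        X <- matrix(as.numeric(Matrix::solve(chol, b)), ncol = 3L)
      }
      cur <- as.matrix(ops$D %*% X)
      # iterate to the fixed point of this stiffness level: a converged
      # solution is independent of the initialization path (and hence of
      # the target's original pose). The criterion uses vertex displacement
      # norms, which are rotation-invariant, so stopping is equivariant.
      if (max(sqrt(rowSums((cur - prev)^2))) < 2e-4) break
    }
    if (trace) {
      d <- .cpp_closest_on_mesh(cur, target@vertices, target@faces)$dist
      stepDist <- c(stepDist, mean(d))
    }
  }
  list(coords = sweep(cur, 2L, ctr, "+"), stepDistances = stepDist)
}

#' Register a template mesh onto a target mesh
#'
#' Deforms the template onto the target in two stages: rigid ICP
#' (rotations and translations only, closed-form orthogonal solution,
#' initialized by centroid and principal-axes superposition with sign
#' disambiguation by minimal surface distance), then an elastic
#' locally-affine non-rigid ICP whose per-vertex affine transforms are
#' penalized for differing across template edges, with the stiffness
#' annealed over `params@elasticSteps`. Correspondences are closest points
#' on the target surface, rejected beyond the search radius or when
#' surface normals disagree by more than the normal limit.
#'
#' The output keeps the template's connectivity and vertex semantics: its
#' vertex `i` is the point on the target surface matching template
#' vertex `i`.
#'
#' @param template template [TriangleMesh-class].
#' @param target target [TriangleMesh-class] of the same bone class,
#'   overlapping the template after centroid alignment.
#' @param params a [RegistrationParams-class]; see [registrationParams()].
#' @param details return diagnostics alongside the shape.
#' @return A [CorrespondedShape-class] (template topology, coordinates on
#'   the target). With `details = TRUE`, a list with elements `shape`,
#'   `meanDistance`, `maxDistance`, `stepDistances` (mean surface distance
#'   after each stiffness step) and `rigidIterations`.
#' @export
registerTemplate <- function(template, target, params = registrationParams(),
                             details = FALSE) {
  validObject(template); validObject(target); validObject(params)
  rigid <- .rigidICP(template@vertices, target, params)
  elastic <- .elasticNICP(rigid$coords, template@faces, target, params,
                          trace = details)
  shape <- CorrespondedShape(elastic$coords, template@faces,
                             templateId = template@name,
                             sourceId = target@name)
  sd <- surfaceDistance(shape, target)
  if (sd$mean > params@distanceTol)
    stop(sprintf(paste0("registration did not reach distance tolerance: mean ",
                        "symmetric surface distance %.3f mm > %.3f mm ",
                        "(max %.3f mm, target '%s')"),
                 sd$mean, params@distanceTol, sd$max, target@name))
  if (!details) return(shape)
  list(shape = shape, meanDistance = sd$mean, maxDistance = sd$max,
       stepDistances = elastic$stepDistances,
       rigidIterations = rigid$iterations)
}
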