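## Low-level mesh geometry shared by registration, alignment and QC.

#' Closest points on a mesh surface
#'
#' For each query point, find the closest point on the triangulated surface
#' (closest point on any triangle, not the nearest vertex).
#'
#' @param points numeric n x 3 matrix of query points (mm).
#' @param mesh a [TriangleMesh-class] or [CorrespondedShape-class].
#' @return list with `points` (n x 3 closest surface points), `dist`
#'   (Euclidean distances, mm) and `tri` (1-based index of the closest
#'   triangle).
#' @export
closestOnMesh <- function(points, mesh) {
  m <- asTriangleMesh(mesh)
  points <- matrix(as.double(points), ncol = 3L)
  .cpp_closest_on_mesh(points, m@vertices, m@faces)
}

#' Per-face unit normals
#' @param mesh mesh-like object.
#' @return m x 3 matrix of unit face normals (right-hand rule on the
#'   stored vertex order).
#' @export
faceNormals <- function(mesh) {
  m <- asTriangleMesh(mesh)
  v <- m@vertices; f <- m@faces
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  n <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
             e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
             e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Per-vertex unit normals (area-weighted average of incident face normals)
#' @param mesh mesh-like object.
#' @return V x 3 matrix of unit vertex normals.
#' @export
vertexNormals <- function(mesh) {
  m <- asTriangleMesh(mesh)
  v <- m@vertices; f <- m@faces
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  fn <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])  # length = 2 * area
  vn <- matrix(0, nrow(v), 3L)
  for (j in 1:3) {
    vn[, 1L] <- vn[, 1L] + tabulate2(f[, j], fn[, 1L], nrow(v))
    vn[, 2L] <- vn[, 2L] + tabulate2(f[, j], fn[, 2L], nrow(v))
    vn[, 3L] <- vn[, 3L] + tabulate2(f[, j], fn[, 3L], nrow(v))
  }
  len <- sqrt(rowSums(vn^2))
  len[len == 0] <- 1
  vn / len
}

# sum weights w by integer bin (1..n); deterministic replacement for rowsum
tabulate2 <- function(bin, w, n) {
  out <- numeric(n)
  agg <- vapply(split(w, bin), sum, numeric(1))
  out[as.integer(names(agg))] <- agg
  out
}

#' Centroid size of a shape
#'
#' Square root of the summed squared distances of all vertices to their
#' centroid -- the standard size measure of geometric morphometrics.
#' Rigid alignment in this package never changes it.
#'
#' @param x mesh-like object or a V x 3 coordinate matrix.
#' @return centroid size (mm).
#' @export
centroidSize <- function(x) {
  v <- if (is.matrix(x)) x else meshVertices(x)
  cc <- sweep(v, 2L, colMeans(v))
  sqrt(sum(cc^2))
}

#' Symmetric surface distance between two surfaces
#'
#' Samples both surfaces at their vertices and measures point-to-surface
#' distances in both directions; returns the mean and maximum over the
#' pooled samples. Zero for identical surfaces; symmetric in its arguments.
#'
#' @param a,b mesh-like objects ([TriangleMesh-class] or
#'   [CorrespondedShape-class]).
#' @return list with `mean` and `max` distance (mm).
#' @export
surfaceDistance <- function(a, b) {
  ma <- asTriangleMesh(a); mb <- asTriangleMesh(b)
  dab <- .cpp_closest_on_mesh(ma@vertices, mb@vertices, mb@faces)$dist
  dba <- .cpp_closest_on_mesh(mb@vertices, ma@vertices, ma@faces)$dist
  d <- c(dab, dba)
  list(mean = mean(d), max = max(d))
}

## ---- rigid transforms -------------------------------------------------

#' Optimal rigid superposition (no scaling)
#'
#' Closed-form least-squares rotation + translation mapping `from` onto
#' `to` over paired points, with a reflection guard: the returned rotation
#' always has determinant +1, so anatomical shapes are never mirrored.
#'
#' @param from,to paired n x 3 coordinate matrices.
#' @param weights optional nonnegative per-point weights.
#' @return list with `R` (3 x 3 proper rotation) and `t` (length-3
#'   translation); the fit is `from %*% t(R) + t` mapped onto `to`.
#' @export
rigidFit <- function(from, to, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(from))
  w <- weights / sum(weights)
  cf <- colSums(from * w)
  ct <- colSums(to * w)
  A <- sweep(from, 2L, cf)
  B <- sweep(to, 2L, ct)
  H <- crossprod(A * w, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- ct - as.numeric(R %*% cf)
  list(R = R, t = t)
}

#' Apply a rigid transform to coordinates
#' @param x V x 3 matrix or mesh-like object.
#' @param transform list with rotation `R` and translation `t`.
#' @return transformed V x 3 matrix.
#' @export
applyRigid <- function(x, transform) {
  v <- if (is.matrix(x)) x else meshVertices(x)
  sweep(v %*% t(transform$R), 2L, transform$t, "+")
}

# principal axes of a point cloud, columns = axes, deterministic order
principalAxes <- function(v) {
  cc <- sweep(v, 2L, colMeans(v))
  eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)$vectors
}

#' Fraction of faces whose orientation flipped relative to a reference
#'
#' Compares face normals of a deformed shape against the same faces on the
#' reference template; a face counts as flipped when the normals point in
#' opposite half-spaces. Used as the self-intersection/folding check after
#' elastic registration.
#'
#' @param shape deformed mesh-like object.
#' @param reference reference mesh-like object with identical topology.
#' @return fraction of flipped faces in `[0, 1]`.
#' @export
flippedFaceFraction <- function(shape, reference) {
  ns <- faceNormals(shape)
  nr <- faceNormals(reference)
  mean(rowSums(ns * nr) < 0)
}
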