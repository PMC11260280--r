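## PCA shape models: construction, projection/reconstruction, compactness,
## leave-one-out generalization, and mode-shape synthesis.

# stack a V x 3 coordinate matrix into (x1,y1,z1,x2,...) vector form
.vecShape <- function(coords) as.vector(t(coords))
.unvecShape <- function(v) matrix(v, ncol = 3L, byrow = TRUE)

.shapeDataMatrix <- function(x) {
  shapes <- if (is(x, "AlignedSet")) x@shapes else x
  do.call(rbind, lapply(shapes, function(s) .vecShape(shapeCoords(s))))
}

#' Build a statistical shape model
#'
#' Computes the arithmetic per-vertex mean shape and the principal modes
#' of shape variation of a set of rigidly aligned corresponded shapes.
#' Modes and variances are the eigenvectors/eigenvalues of the sample
#' covariance (divisor n - 1) of the mean-centered shape vectors, computed
#' through the singular-value decomposition of the centered data matrix.
#' Mode signs are fixed deterministically (largest-magnitude coefficient
#' positive), so repeated builds are identical.
#'
#' @param x an [AlignedSet-class], or a list of aligned
#'   [CorrespondedShape-class] objects.
#' @return A [ShapeModel-class] with `min(3V, n - 1)` modes (tiny negative
#'   variances clipped to zero).
#' @export
buildShapeModel <- function(x) {
  shapes <- if (is(x, "AlignedSet")) x@shapes else x
  if (length(shapes) < 2L) stop("need at least 2 shapes to build a shape model")
  .checkSameTemplate(shapes)
  X <- .shapeDataMatrix(shapes)
  n <- nrow(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc, nu = 0, nv = min(n - 1L, ncol(X)))
  k <- ncol(sv$v)
  variances <- pmax(sv$d[seq_len(k)]^2 / (n - 1L), 0)
  modes <- sv$v
  for (j in seq_len(k)) {
    i <- which.max(abs(modes[, j]))
    if (modes[i, j] < 0) modes[, j] <- -modes[, j]
  }
  new("ShapeModel", templateId = shapes[[1L]]@templateId, mean = mu,
      modes = modes, variances = variances, nTrain = as.integer(n),
      faces = shapes[[1L]]@faces)
}

#' Project a shape onto model modes (PC weights)
#'
#' Returns the least-squares optimal coefficients of the shape on the
#' first `nModes` modes. Unless `align = FALSE`, the shape is first
#' rigidly aligned (rotation + translation, never scaling) to the model
#' mean, so the weights describe pose-free morphology and size information
#' is retained.
#'
#' @param model a [ShapeModel-class].
#' @param shape a [CorrespondedShape-class] on the model's template, or a
#'   V x 3 coordinate matrix.
#' @param nModes number of leading modes (default: all retained).
#' @param align apply the internal rigid alignment to the model mean.
#' @return numeric vector of PC weights (mm), length `nModes`.
#' @export
projectShape <- function(model, shape, nModes = numModes(model), align = TRUE) {
  if (nModes > numModes(model))
    stop("nModes (", nModes, ") exceeds the model's retained modes (",
         numModes(model), ")")
  coords <- if (is.matrix(shape)) shape else shapeCoords(shape)
  if (nrow(coords) * 3L != length(model@mean))
    stop("shape is not on the model's template")
  if (align) {
    mu <- .unvecShape(model@mean)
    coords <- applyRigid(coords, rigidFit(coords, mu))
  }
  as.numeric(crossprod(model@modes[, seq_len(nModes), drop = FALSE],
                       .vecShape(coords) - model@mean))
}

#' Reconstruct a shape from PC weights
#'
#' @param model a [ShapeModel-class].
#' @param weights numeric vector of PC weights for the leading modes.
#' @param nModes number of modes used; must equal `length(weights)`.
#' @return A [CorrespondedShape-class]: mean + sum of weighted modes.
#' @export
reconstructShape <- function(model, weights, nModes = length(weights)) {
  if (length(weights) != nModes)
    stop("length(weights) must equal nModes")
  if (nModes > numModes(model)) stop("nModes exceeds the retained modes")
  v <- model@mean
  if (nModes > 0L)
    v <- v + as.numeric(model@modes[, seq_len(nModes), drop = FALSE] %*% weights)
  CorrespondedShape(.unvecShape(v), model@faces,
                    templateId = model@templateId, sourceId = "reconstruction")
}

#' Model compactness curve
#'
#' Cumulative explained-variance ratio as a function of the number of
#' modes. Compact models describe population shape variation with few
#' modes.
#'
#' @param model a [ShapeModel-class] with at least one positive variance.
#' @return data.frame with columns `modes` and `cumulative` (final entry
#'   1 within 1e-12).
#' @export
modelCompactness <- function(model) {
  v <- model@variances
  tv <- sum(v)
  if (tv <= 0) stop("all mode variances are zero; compactness undefined")
  data.frame(modes = seq_along(v), cumulative = cumsum(v) / tv)
}

#' Smallest mode count reaching a cumulative variance threshold
#'
#' @param model a [ShapeModel-class].
#' @param threshold cumulative explained-variance ratio, e.g. the 0.98
#'   used throughout this package for retaining modes.
#' @return integer mode count.
#' @export
modesForVariance <- function(model, threshold = 0.98) {
  curve <- modelCompactness(model)
  k <- which(curve$cumulative >= threshold - 1e-12)
  if (!length(k)) stop("threshold not reached by any mode count")
  as.integer(k[1L])
}

#' Leave-one-out generalization curve
#'
#' For every shape in turn, a model is rebuilt on the remaining shapes,
#' the left-out shape is projected and reconstructed with increasing
#' numbers of modes, and the description error is recorded as the root
#' mean square over vertices of the Euclidean reconstruction error. The
#' curve is the mean over all leave-one-out experiments; every sample is
#' left out exactly once.
#'
#' @param x an [AlignedSet-class] (or list of aligned shapes) with at
#'   least 3 shapes.
#' @param maxModes largest mode count evaluated; at most n - 2.
#' @return data.frame with columns `modes` (0..maxModes) and `rmse` (mm);
#'   attribute `repeats` holds the number of leave-one-out experiments.
#' @export
generalizationLOO <- function(x, maxModes = NULL) {
  shapes <- if (is(x, "AlignedSet")) x@shapes else x
  n <- length(shapes)
  if (n < 3L) stop("need at least 3 shapes for leave-one-out generalization")
  if (is.null(maxModes)) maxModes <- n - 2L
  if (maxModes > n - 2L)
    stop("maxModes (", maxModes, ") exceeds n - 2 = ", n - 2L)
  V <- nrow(shapes[[1L]]@coordinates)
  err <- matrix(NA_real_, n, maxModes + 1L)
  for (i in seq_len(n)) {
    model <- buildShapeModel(shapes[-i])
    kmax <- min(maxModes, numModes(model))
    mu <- .unvecShape(model@mean)
    coords <- shapeCoords(shapes[[i]])
    coords <- applyRigid(coords, rigidFit(coords, mu))
    resid <- .vecShape(coords) - model@mean
    w <- as.numeric(crossprod(model@modes[, seq_len(kmax), drop = FALSE], resid))
    # orthonormal modes: residual norm after k modes shrinks by sum(w[1:k]^2)
    sq <- sum(resid^2) - cumsum(c(0, w^2))
    sq <- pmax(sq, 0)
    rmse <- sqrt(sq / V)
    err[i, seq_len(kmax + 1L)] <- rmse
    if (kmax < maxModes) err[i, (kmax + 2L):(maxModes + 1L)] <- rmse[kmax + 1L]
  }
  out <- data.frame(modes = 0:maxModes, rmse = colMeans(err))
  attr(out, "repeats") <- n
  out
}

#' Synthesize mode shapes at multiples of a mode's standard deviation
#'
#' Renders the shape at `mean + k * sigma_i * mode_i` for each `k`, the
#' standard way of visualizing what a mode of shape variation encodes.
#'
#' @param model a [ShapeModel-class].
#' @param modeIndex which mode (1-based).
#' @param kList multiples of the mode standard deviation (e.g. `c(-2, 2)`).
#' @return named list of [CorrespondedShape-class], one per `k`.
#' @export
modeShapes <- function(model, modeIndex, kList = c(-2, 0, 2)) {
  if (modeIndex < 1L || modeIndex > numModes(model))
    stop("invalid mode index ", modeIndex)
  sdev <- sqrt(model@variances[modeIndex])
  out <- lapply(kList, function(k) {
    v <- model@mean + k * sdev * model@modes[, modeIndex]
    CorrespondedShape(.unvecShape(v), model@faces,
                      templateId = model@templateId,
                      sourceId = sprintf("mode%d_%+gSD", modeIndex, k))
  })
  names(out) <- sprintf("%+gSD", kList)
  out
}
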