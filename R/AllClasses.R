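#' @import methods
#' @importFrom stats cor cor.test chisq.test fisher.test t.test pt pchisq
#'   quantile rnorm runif rbinom sd var qnorm plogis prcomp setNames
#' @importFrom utils read.csv write.csv head
#' @useDynLib kneeSSM, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## ---- TriangleMesh -----------------------------------------------------

#' Triangular surface mesh
#'
#' A raw 3D bone surface: an ordered set of vertices (millimetres) and an
#' ordered set of triangles given as 1-based vertex-index triples. Vertex
#' order in a raw mesh carries no anatomical meaning; readers preserve the
#' file order without reindexing. Correspondence across specimens is
#' established downstream (see [registerTemplate()]).
#'
#' @slot vertices numeric matrix, one row per vertex, columns x/y/z in mm.
#' @slot faces integer matrix, one row per triangle, 1-based vertex indices.
#' @slot name free-text label (e.g. `"femur_P012"`).
#' @export
setClass("TriangleMesh",
  representation(vertices = "matrix", faces = "matrix", name = "character"),
  prototype(name = ""))

setValidity("TriangleMesh", function(object) {
  v <- object@vertices; f <- object@faces
  if (!is.numeric(v) || ncol(v) != 3L) return("vertices must be a numeric n x 3 matrix")
  if (nrow(v) < 1L) return("mesh must have at least one vertex")
  if (!all(is.finite(v))) return("all vertex coordinates must be finite")
  if (ncol(f) != 3L) return("faces must be an n x 3 index matrix")
  if (nrow(f) < 1L) return("mesh must have at least one face")
  fi <- as.integer(f)
  if (any(is.na(fi)) || any(fi < 1L) || any(fi > nrow(v)))
    return("every face index must be a valid vertex index")
  if (any(f[, 1L] == f[, 2L] | f[, 1L] == f[, 3L] | f[, 2L] == f[, 3L]))
    return("the three vertex indices of a face must be distinct")
  TRUE
})

#' Construct a TriangleMesh
#'
#' @param vertices numeric n x 3 matrix of coordinates (mm).
#' @param faces integer m x 3 matrix of 1-based vertex indices.
#' @param name optional label.
#' @return A validated [TriangleMesh-class] object.
#' @export
TriangleMesh <- function(vertices, faces, name = "") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  new("TriangleMesh", vertices = vertices, faces = faces, name = as.character(name)[1L])
}

setMethod("show", "TriangleMesh", function(object) {
  cat(sprintf("TriangleMesh '%s': %d vertices, %d faces (mm)\n",
              object@name, nrow(object@vertices), nrow(object@faces)))
})

#' @describeIn TriangleMesh-class vertex coordinate matrix (mm).
#' @param mesh,x a mesh-like object.
#' @export
meshVertices <- function(mesh) {
  if (is(mesh, "CorrespondedShape")) return(mesh@coordinates)
  mesh@vertices
}

#' @describeIn TriangleMesh-class face index matrix.
#' @export
meshFaces <- function(mesh) mesh@faces

## ---- CorrespondedShape ------------------------------------------------

#' Corresponded shape
#'
#' Coordinates of one specimen expressed on a shared template: vertex `i`
#' marks the same anatomical location (pseudo-landmark) on every specimen.
#' Vertex order is therefore semantic. The template's triangulation is
#' carried along so the shape can still be rendered and measured as a mesh.
#'
#' @slot templateId identifier of the template the shape lives on.
#' @slot coordinates numeric V x 3 matrix (mm), V = template vertex count.
#' @slot sourceId label of the specimen (patient/bone) the shape describes.
#' @slot faces template triangulation (integer m x 3).
#' @export
setClass("CorrespondedShape",
  representation(templateId = "character", coordinates = "matrix",
                 sourceId = "character", faces = "matrix"))

setValidity("CorrespondedShape", function(object) {
  cc <- object@coordinates
  if (!is.numeric(cc) || ncol(cc) != 3L) return("coordinates must be a numeric V x 3 matrix")
  if (!all(is.finite(cc))) return("coordinates must be finite")
  if (nrow(object@faces) >= 1L) {
    fi <- as.integer(object@faces)
    if (any(fi < 1L) || any(fi > nrow(cc)))
      return("faces refer to vertices outside the template")
  }
  TRUE
})

#' Construct a CorrespondedShape
#' @param coordinates numeric V x 3 matrix (mm).
#' @param faces template triangulation.
#' @param templateId,sourceId labels.
#' @return A [CorrespondedShape-class] object.
#' @export
CorrespondedShape <- function(coordinates, faces, templateId = "template",
                              sourceId = "") {
  coordinates <- as.matrix(coordinates)
  storage.mode(coordinates) <- "double"
  dimnames(coordinates) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  new("CorrespondedShape", templateId = as.character(templateId)[1L],
      coordinates = coordinates, sourceId = as.character(sourceId)[1L],
      faces = faces)
}

setMethod("show", "CorrespondedShape", function(object) {
  cat(sprintf("CorrespondedShape '%s' on template '%s': %d vertices\n",
              object@sourceId, object@templateId, nrow(object@coordinates)))
})

#' Coordinates of a corresponded shape
#' @param shape a [CorrespondedShape-class].
#' @return numeric V x 3 matrix (mm).
#' @export
shapeCoords <- function(shape) shape@coordinates

#' View a corresponded shape as a TriangleMesh
#' @param shape a [CorrespondedShape-class].
#' @return a [TriangleMesh-class] with the template triangulation.
#' @export
asTriangleMesh <- function(shape) {
  if (is(shape, "TriangleMesh")) return(shape)
  TriangleMesh(shape@coordinates, shape@faces, name = shape@sourceId)
}

## ---- RegistrationParams ----------------------------------------------

#' Registration parameters
#'
#' Controls the rigid and elastic stages of template registration. The
#' elastic stiffness schedule must be strictly decreasing and positive:
#' high stiffness keeps the deformation near-rigid early on, low stiffness
#' lets the template relax onto fine surface detail at the end.
#'
#' @slot rigidMaxIters maximum rigid ICP iterations.
#' @slot elasticSteps strictly decreasing positive stiffness schedule.
#' @slot searchRadius correspondence search radius (mm); closest-point
#'   matches farther than this are dropped for the iteration.
#' @slot convergenceTol rigid-stage RMS-change convergence tolerance (mm).
#' @slot distanceTol acceptable final mean symmetric surface distance (mm).
#' @slot normalLimitDeg matches whose surface normals disagree by more than
#'   this angle (degrees) are rejected.
#' @slot elasticInnerIters cap on inner iterations per stiffness step;
#'   each step stops early once the update falls below 1e-4 mm.
#' @slot planeBlend tangential relaxation of the correspondence target in
#'   `[0, 1]`: 0 pulls straight toward the closest surface point
#'   (point-to-point), 1 constrains only the surface-normal component
#'   (point-to-plane style), leaving tangential placement to the
#'   stiffness prior so correspondence does not slide along steep relief.
#' @export
setClass("RegistrationParams",
  representation(rigidMaxIters = "numeric", elasticSteps = "numeric",
                 searchRadius = "numeric", convergenceTol = "numeric",
                 distanceTol = "numeric", normalLimitDeg = "numeric",
                 elasticInnerIters = "numeric", planeBlend = "numeric"))

setValidity("RegistrationParams", function(object) {
  s <- object@elasticSteps
  if (length(s) < 1L || any(s <= 0)) return("stiffness schedule must be positive")
  if (length(s) > 1L && any(diff(s) >= 0)) return("stiffness schedule must be strictly decreasing")
  for (nm in c("searchRadius", "convergenceTol", "distanceTol"))
    if (slot(object, nm) <= 0) return(sprintf("%s must be > 0", nm))
  if (object@planeBlend < 0 || object@planeBlend > 1)
    return("planeBlend must lie in [0, 1]")
  if (object@rigidMaxIters < 1) return("rigidMaxIters must be >= 1")
  TRUE
})

#' Construct registration parameters
#'
#' Defaults: 8 elastic stiffness steps with geometric decay, 0.5 mm distance
#' tolerance (strict but attainable on the synthetic meshes this package
#' generates), 20 mm search radius, 60 degree normal-compatibility limit.
#'
#' @param rigidMaxIters maximum rigid ICP iterations.
#' @param elasticSteps stiffness schedule (strictly decreasing, positive).
#' @param searchRadius correspondence search radius in mm.
#' @param convergenceTol rigid convergence tolerance in mm.
#' @param distanceTol required final mean surface distance in mm.
#' @param normalLimitDeg normal-compatibility limit in degrees.
#' @param elasticInnerIters cap on inner iterations per stiffness step.
#' @param planeBlend tangential relaxation of the match target (0 =
#'   point-to-point, 1 = point-to-plane style); see the class docs.
#' @return A [RegistrationParams-class] object.
#' @export
registrationParams <- function(rigidMaxIters = 50,
                               elasticSteps = 50 * 0.55^(0:7),
                               searchRadius = 20,
                               convergenceTol = 1e-6,
                               distanceTol = 0.5,
                               normalLimitDeg = 60,
                               elasticInnerIters = 6,
                               planeBlend = 0) {
  new("RegistrationParams", rigidMaxIters = rigidMaxIters,
      elasticSteps = elasticSteps, searchRadius = searchRadius,
      convergenceTol = convergenceTol, distanceTol = distanceTol,
      normalLimitDeg = normalLimitDeg, elasticInnerIters = elasticInnerIters,
      planeBlend = planeBlend)
}

## ---- VertexMask -------------------------------------------------------

#' Vertex inclusion mask
#'
#' Marks which template vertices belong to the analysis region (e.g. the
#' distal femur / proximal tibia portion kept after cropping away the bone
#' shaft, whose extent depends on the scan field of view).
#'
#' @slot templateId template the mask refers to.
#' @slot include logical vector, one entry per template vertex.
#' @export
setClass("VertexMask",
  representation(templateId = "character", include = "logical"))

setValidity("VertexMask", function(object) {
  if (length(object@include) < 1L) return("mask must have at least one entry")
  if (any(is.na(object@include))) return("mask entries must be TRUE/FALSE")
  if (!any(object@include)) return("mask must include at least one vertex")
  TRUE
})

#' Construct a vertex mask
#' @param include logical vector over template vertices.
#' @param templateId template label.
#' @return A [VertexMask-class].
#' @export
VertexMask <- function(include, templateId = "template") {
  new("VertexMask", templateId = as.character(templateId)[1L],
      include = as.logical(include))
}

## ---- AlignedSet -------------------------------------------------------

#' Rigidly co-aligned shape set
#'
#' The result of generalized Procrustes alignment without scaling: all
#' shapes share one coordinate frame, the mean of the shape centroids sits
#' at the origin, and the per-shape transform (proper rotation plus
#' translation) that produced each aligned shape is retained. Centroid
#' sizes are untouched -- overall size remains a mode of shape variation.
#'
#' @slot shapes list of [CorrespondedShape-class] in the common frame.
#' @slot meanShape the Procrustes mean shape.
#' @slot transforms list of `list(R = 3x3, t = length-3)` per input shape.
#' @slot templateId common template.
#' @export
setClass("AlignedSet",
  representation(shapes = "list", meanShape = "CorrespondedShape",
                 transforms = "list", templateId = "character"))

setValidity("AlignedSet", function(object) {
  if (length(object@shapes) < 1L) return("empty aligned set")
  cent <- colMeans(do.call(rbind, lapply(object@shapes, function(s) colMeans(s@coordinates))))
  if (max(abs(cent)) > 1e-6) return("mean of shape centroids must be at the origin (1e-6 mm)")
  for (tr in object@transforms) {
    if (abs(det(tr$R) - 1) > 1e-6) return("stored rotations must be proper (det = +1)")
  }
  TRUE
})

setMethod("show", "AlignedSet", function(object) {
  cat(sprintf("AlignedSet on template '%s': %d shapes, %d vertices each\n",
              object@templateId, length(object@shapes),
              nrow(object@meanShape@coordinates)))
})

#' @describeIn AlignedSet-class list of aligned shapes.
#' @param x an AlignedSet.
#' @export
alignedShapes <- function(x) x@shapes

#' @describeIn AlignedSet-class the Procrustes mean shape.
#' @export
meanShape <- function(x) x@meanShape

## ---- ShapeModel -------------------------------------------------------

#' Statistical shape model
#'
#' Mean shape plus orthonormal modes of shape variation with per-mode
#' variances (PCA of the aligned training shapes, covariance divisor
#' n - 1). Any shape of the same nature is described as the mean plus a
#' weighted sum of modes; the weights are the principal-component (PC)
#' weights that downstream statistics and prediction operate on.
#'
#' @slot templateId template the model lives on.
#' @slot mean mean shape as a length-3V vector (x1,y1,z1,x2,...).
#' @slot modes 3V x k matrix of orthonormal mode vectors.
#' @slot variances per-mode variance (mm^2), nonincreasing.
#' @slot nTrain number of training shapes.
#' @slot faces template triangulation (for rendering mode shapes).
#' @export
setClass("ShapeModel",
  representation(templateId = "character", mean = "numeric",
                 modes = "matrix", variances = "numeric",
                 nTrain = "integer", faces = "matrix"))

setValidity("ShapeModel", function(object) {
  k <- ncol(object@modes)
  if (length(object@variances) != k) return("one variance per mode required")
  if (k > 0L) {
    if (any(diff(object@variances) > 1e-9)) return("variances must be nonincreasing")
    if (any(object@variances < -1e-12)) return("variances must be >= 0")
    g <- crossprod(object@modes)
    if (max(abs(g - diag(k))) > 1e-8) return("modes must be orthonormal (1e-8)")
    if (k > min(length(object@mean), object@nTrain - 1L))
      return("mode count exceeds min(3V, n - 1)")
  }
  TRUE
})

setMethod("show", "ShapeModel", function(object) {
  tv <- sum(object@variances)
  k98 <- if (tv > 0) modesForVariance(object, 0.98) else NA_integer_
  cat(sprintf("ShapeModel '%s': %d vertices, %d training shapes, %d modes\n",
              object@templateId, length(object@mean) / 3L, object@nTrain,
              ncol(object@modes)))
  cat(sprintf("  total variance %.4g mm^2; 98%% of variance in %s modes\n",
              tv, as.character(k98)))
})

#' @describeIn ShapeModel-class mean shape as a V x 3 matrix (mm).
#' @param model a ShapeModel.
#' @export
modelMean <- function(model) matrix(model@mean, ncol = 3L, byrow = TRUE)

#' @describeIn ShapeModel-class orthonormal mode matrix (3V x k).
#' @export
modelModes <- function(model) model@modes

#' @describeIn ShapeModel-class per-mode variances (mm^2).
#' @export
modelVariances <- function(model) model@variances

#' @describeIn ShapeModel-class number of retained modes.
#' @export
numModes <- function(model) ncol(model@modes)

## ---- PredictionResult -------------------------------------------------

#' Outcome-prediction result
#'
#' Per-patient leave-one-out probabilities of response to treatment
#' (class R coded 1, MPMS coded 0), predicted labels at the classification
#' threshold, and summary metrics (sensitivity/specificity for detecting
#' each class, ROC-AUC) with stratified-bootstrap percentile confidence
#' intervals.
#'
#' @slot labels true labels (1 = R, 0 = MPMS).
#' @slot probabilities LOO probability of class R per patient.
#' @slot predicted predicted label at the threshold.
#' @slot threshold classification threshold on P(R).
#' @slot metrics data.frame with columns metric, value, lower, upper.
#' @slot nBoot bootstrap iteration count.
#' @slot seed RNG seed used for the bootstrap.
#' @slot modelName which shape model fed the classifier.
#' @export
setClass("PredictionResult",
  representation(labels = "integer", probabilities = "numeric",
                 predicted = "integer", threshold = "numeric",
                 metrics = "data.frame", nBoot = "integer",
                 seed = "integer", modelName = "character"))

setValidity("PredictionResult", function(object) {
  p <- object@probabilities
  if (any(p < 0 | p > 1)) return("probabilities must lie in [0, 1]")
  if (length(p) != length(object@labels)) return("one probability per label required")
  m <- object@metrics
  if (nrow(m)) {
    if (any(m$value < -1e-12 | m$value > 1 + 1e-12)) return("metrics must lie in [0, 1]")
    bad <- !is.na(m$lower) & (m$lower > m$value + 1e-12 | m$upper < m$value - 1e-12)
    if (any(bad)) return("CI must bracket the point estimate")
  }
  TRUE
})

setMethod("show", "PredictionResult", function(object) {
  cat(sprintf("PredictionResult (%s): n = %d, threshold %.2f, %d bootstrap draws\n",
              object@modelName, length(object@labels), object@threshold,
              object@nBoot))
  m <- object@metrics
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %-18s %.3f (95%% CI %.3f-%.3f)\n",
                m$metric[i], m$value[i], m$lower[i], m$upper[i]))
})

#' @describeIn PredictionResult-class metric table with CIs.
#' @param x a PredictionResult.
#' @export
predictionMetrics <- function(x) x@metrics
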