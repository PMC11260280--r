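## Synthetic bone-shaped cohort generator.
##
## Emulates the statistical structure of a two-group (responder vs medial
## postmeniscectomy syndrome) knee-morphology study: parametric femur- and
## tibia-like surface patches with interpretable shape handles, three
## planted orthonormal modes of shape variation (overall size,
## intercondylar-notch width, medial-condyle width) with group-conditional
## score distributions, matched demographics, KOOS subscores respecting
## the pain split at 75, and spatially correlated residual surface noise.
## Everything is deterministic under the cohort specification's seed.

## ---- parametric templates --------------------------------------------

.gridFaces <- function(nu, nv) {
  f <- matrix(0L, 2L * (nu - 1L) * (nv - 1L), 3L)
  k <- 1L
  for (j in seq_len(nv - 1L)) for (i in seq_len(nu - 1L)) {
    a <- (j - 1L) * nu + i
    f[k, ] <- c(a, a + 1L, a + nu); k <- k + 1L
    f[k, ] <- c(a + 1L, a + nu + 1L, a + nu); k <- k + 1L
  }
  f
}

# distal-femur-like patch: two condylar lobes (medial slightly larger,
# breaking mirror symmetry so rigid alignment cannot flip sides) separated
# by an intercondylar groove. x: medial(-) to lateral(+), y: anterior(-)
# to posterior(+), z: condylar relief. Units mm at size = 1.
.femurSurface <- function(u, v, size = 1, notch = 1, condyle = 1) {
  x <- 70 * (u - 0.5)
  y <- 50 * (v - 0.5)
  lobeM <- 13 * exp(-((x + 18)^2) / (2 * (10 * condyle)^2) - (y - 2)^2 / (2 * 18^2))
  lobeL <- 11 * exp(-((x - 18)^2) / (2 * 8.5^2) - (y + 1)^2 / (2 * 17^2))
  groove <- -8 * exp(-x^2 / (2 * (6 * notch)^2) - y^2 / (2 * 14^2))
  z <- -0.004 * x^2 - 0.008 * y^2 + lobeM + lobeL + groove
  size * cbind(x, y, z)
}

# proximal-tibia-like patch: gently dished plateau with two central spine
# bumps (medial higher) and a deeper medial-side concavity.
.tibiaSurface <- function(u, v, size = 1, spine = 1, interspine = 1) {
  x <- 70 * (u - 0.5)
  y <- 48 * (v - 0.5)
  spM <- 9.0 * spine * exp(-(((x + 6 * interspine)^2) + 0.8 * y^2) / (2 * 5.5^2))
  spL <- 7.5 * spine * exp(-(((x - 6 * interspine)^2) + 0.8 * y^2) / (2 * 5.5^2))
  dishM <- -2.5 * exp(-((x + 20)^2 + y^2) / (2 * 12^2))
  dishL <- -1.5 * exp(-((x - 20)^2 + y^2) / (2 * 12^2))
  z <- -0.003 * x^2 - 0.004 * y^2 + spM + spL + dishM + dishL
  size * cbind(x, y, z)
}

# remove net rigid motion (translations + infinitesimal rotations) from
# stacked displacement fields, the component GPA removes downstream
.projectOutRigid <- function(fields, vertices) {
  Vc <- sweep(vertices, 2L, colMeans(vertices))
  nV <- nrow(vertices)
  rig <- cbind(rep(c(1, 0, 0), nV), rep(c(0, 1, 0), nV), rep(c(0, 0, 1), nV),
               .vecShape(cbind(-Vc[, 2L], Vc[, 1L], 0)),
               .vecShape(cbind(-Vc[, 3L], 0, Vc[, 1L])),
               .vecShape(cbind(0, -Vc[, 3L], Vc[, 2L])))
  Q <- qr.Q(qr(rig))
  fields - Q %*% crossprod(Q, fields)
}

.gramSchmidt <- function(fields) {
  out <- NULL
  for (j in seq_len(ncol(fields))) {
    v <- fields[, j]
    if (!is.null(out)) v <- v - out %*% crossprod(out, v)
    v <- v / sqrt(sum(v^2))
    out <- cbind(out, as.numeric(v))
  }
  out
}

#' Generate a synthetic bone template
#'
#' Builds a smooth parametric bone-like surface patch with fixed topology
#' (a `resolution` x `resolution` vertex grid) and interpretable shape
#' handles: overall `size` (scales centroid size exactly linearly),
#' `notch` (femur: intercondylar groove width) and `condyle` (femur:
#' medial-condyle width), or `spine` (tibia: spine height) and
#' `interspine` (tibia: spine separation). Repeated calls with identical
#' arguments are identical.
#'
#' Besides the mesh, the result carries the orthonormalized displacement
#' fields of the three handles (Gram-Schmidt on the handle derivative
#' fields, in the order size, notch/interspine, condyle/spine), which the
#' cohort generator uses as planted modes, and a default analysis mask
#' that drops the two vertex rows nearest the bone shaft.
#'
#' Because a surface determines a displacement field only up to tangential
#' reparametrization, the raw handle derivatives are gauge-fixed by
#' `gaugeIters` fixed-point iterations of the package's elastic
#' registration: each field is replaced by the deformation the
#' registration recovers for it (net rigid motion removed), then the set
#' is re-orthonormalized. The planted modes are therefore the
#' registration-consistent representatives of the handle fields -- the
#' same convention any correspondence-based shape model imposes on real
#' data. `gaugeIters = 0` skips this and returns the raw orthonormalized
#' derivatives.
#'
#' @param bone `"femur"` or `"tibia"`.
#' @param resolution grid vertices per side (6 to 80).
#' @param size,notch,condyle,spine,interspine shape handles (1 = neutral).
#' @param gaugeIters fixed-point iterations of the registration gauge map.
#' @param gaugeAmplitudes per-field evaluation amplitudes (mm) for the
#'   gauge map, matched to the default cohort's 2 SD excursions.
#' @param params registration parameters used for the gauge map (must
#'   match the registration the cohort is analysed with).
#' @return list with `mesh` ([TriangleMesh-class]), `fields` (3V x 3
#'   orthonormal matrix, columns size/notch/condyle analogues), `mask`
#'   ([VertexMask-class]) and the grid coordinates `u`, `v`.
#' @export
makeTemplate <- function(bone = c("femur", "tibia"), resolution = 14,
                         size = 1, notch = 1, condyle = 1, spine = 1,
                         interspine = 1, gaugeIters = 8,
                         gaugeAmplitudes = c(16, 4, 3),
                         params = registrationParams()) {
  bone <- match.arg(bone)
  if (resolution < 6 || resolution > 80)
    stop("resolution must be between 6 and 80")
  n <- as.integer(resolution)
  g <- expand.grid(u = seq(0, 1, length.out = n), v = seq(0, 1, length.out = n))
  surf <- if (bone == "femur") {
    function(s, no, co) .femurSurface(g$u, g$v, s, no, co)
  } else {
    function(s, no, co) .tibiaSurface(g$u, g$v, s, spine = co, interspine = no)
  }
  base <- surf(size, if (bone == "femur") notch else interspine,
               if (bone == "femur") condyle else spine)
  mesh <- TriangleMesh(base, .gridFaces(n, n),
                       name = sprintf("%s_template", bone))
  # handle derivative fields at the neutral configuration, stacked 3V
  h <- 1e-4
  d1 <- .vecShape(surf(1 + h, 1, 1) - surf(1, 1, 1)) / h
  d2 <- .vecShape(surf(1, 1 + h, 1) - surf(1, 1, 1)) / h
  d3 <- .vecShape(surf(1, 1, 1 + h) - surf(1, 1, 1)) / h
  fields <- .gramSchmidt(.projectOutRigid(cbind(d1, d2, d3), base))
  baseVec <- .vecShape(base)
  L <- function(f, a) {
    tgt <- TriangleMesh(.unvecShape(baseVec + a * f), mesh@faces, "gauge")
    (.vecShape(shapeCoords(registerTemplate(mesh, tgt, params))) -
       baseVec) / a
  }
  for (it in seq_len(gaugeIters)) {
    # symmetric (+/- amplitude) response, damped half-step: centres the
    # representative on the score distribution rather than one excursion
    rec <- vapply(1:3, function(k) {
      a <- gaugeAmplitudes[k]
      (L(fields[, k], a) + L(fields[, k], -a)) / 2
    }, numeric(length(baseVec)))
    fields <- .gramSchmidt(.projectOutRigid(0.5 * fields + 0.5 * rec, base))
  }
  colnames(fields) <- if (bone == "femur") c("size", "notch", "condyle")
                      else c("size", "interspine", "spine")
  vrow <- rep(seq_len(n), each = n)  # v index per vertex
  mask <- VertexMask(vrow <= n - 2L, templateId = mesh@name)
  list(mesh = mesh, fields = fields, mask = mask, u = g$u, v = g$v)
}

## ---- cohort specification --------------------------------------------

#' Specify a synthetic cohort
#'
#' Default values define the package's reference study conditions:
#' 120 patients per group; three planted modes with population SDs (in mm
#' of orthonormal-field coefficient) of 8 (size), 2 (notch width) and 1.5
#' (medial-condyle width); MPMS-vs-R mean shifts of -1.0, +0.8 and -0.6
#' population SDs (MPMS knees smaller, with a wider notch and a narrower
#' medial condyle); residual surface noise of 0.1 mm per coordinate,
#' spatially correlated with a geometrically decaying spectrum; matched
#' demographics; and KOOS pain respecting the split at 75 by construction.
#'
#' @param nR,nMPMS patients per group (>= 2).
#' @param sizeSD,notchSD,condyleSD planted per-mode population SDs (mm).
#' @param shiftSize,shiftNotch,shiftCondyle MPMS-minus-R mean shift of
#'   each mode score, in units of the mode SD.
#' @param noiseSD residual surface noise per vertex (mm): the RMS 3D
#'   displacement magnitude of a vertex (isotropic, so the per-coordinate
#'   SD is `noiseSD / sqrt(3)`).
#' @param femaleProportion cohort female fraction.
#' @param sexSizeCor target correlation between sex and the size score.
#' @param poseMaxAngle,poseMaxShift bounds of the random rigid pose given
#'   to each generated bone (degrees, mm), emulating patient positioning
#'   in the scanner.
#' @param resolution template grid resolution.
#' @param registration [registrationParams()] used both for the template
#'   gauge fixing and intended for the downstream analysis.
#' @param gaugeIters gauge-fixing iterations for the templates (see
#'   [makeTemplate()]); small fixture cohorts can use fewer.
#' @param seed RNG seed.
#' @param meshes generate meshes (FALSE = records and ground truth only).
#' @return A `cohortSpec` list.
#' @export
cohortSpec <- function(nR = 120, nMPMS = 120,
                       sizeSD = 8, notchSD = 2, condyleSD = 1.5,
                       shiftSize = -1.0, shiftNotch = 0.8, shiftCondyle = -0.6,
                       noiseSD = 0.1, femaleProportion = 0.27,
                       sexSizeCor = 0.75, poseMaxAngle = 25,
                       poseMaxShift = 30, resolution = 14,
                       registration = registrationParams(), gaugeIters = 8,
                       seed = 1, meshes = TRUE) {
  if (nR < 2 || nMPMS < 2) stop("infeasible spec: need at least 2 per group")
  if (any(c(sizeSD, notchSD, condyleSD, noiseSD) < 0))
    stop("infeasible spec: SDs must be >= 0")
  if (!all(is.finite(c(shiftSize, shiftNotch, shiftCondyle))))
    stop("infeasible spec: shifts must be finite")
  spec <- list(nR = nR, nMPMS = nMPMS, sizeSD = sizeSD, notchSD = notchSD,
               condyleSD = condyleSD, shiftSize = shiftSize,
               shiftNotch = shiftNotch, shiftCondyle = shiftCondyle,
               noiseSD = noiseSD, femaleProportion = femaleProportion,
               sexSizeCor = sexSizeCor, poseMaxAngle = poseMaxAngle,
               poseMaxShift = poseMaxShift, resolution = resolution,
               registration = registration, gaugeIters = gaugeIters,
               seed = seed, meshes = meshes,
               # tibia expression of the planted modes (mm of field
               # coefficient per unit score); the notch/condyle analogues
               # carry the same population SD as on the femur
               tibiaCoef = c(size = 0.875 * sizeSD, notch = notchSD,
                             condyle = condyleSD))
  class(spec) <- "cohortSpec"
  spec
}

# smooth orthonormal noise basis on the template grid: low-order tensor
# cosines per coordinate axis, ordered by total frequency
.noiseBasis <- function(u, v, nFields = 100L) {
  orders <- expand.grid(p = 0:8, q = 0:8, axis = 1:3)
  orders <- orders[order(orders$p + orders$q, orders$p, orders$axis), ]
  orders <- orders[orders$p + orders$q > 0, ][seq_len(nFields), ]
  V <- length(u)
  B <- matrix(0, 3L * V, nFields)
  for (j in seq_len(nFields)) {
    g <- cos(pi * orders$p[j] * u) * cos(pi * orders$q[j] * v)
    fld <- matrix(0, V, 3L)
    fld[, orders$axis[j]] <- g
    B[, j] <- .vecShape(fld)
  }
  .gramSchmidt(B)
}

.randomRigidPose <- function(maxAngleDeg = 25, maxShift = 30) {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, maxAngleDeg * pi / 180)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  list(R = R, t = runif(3, -maxShift, maxShift))
}

## ---- cohort generation ------------------------------------------------

#' Generate a synthetic two-group cohort
#'
#' Draws per-patient scores for the three planted modes from
#' group-conditional normal distributions (unit SD, MPMS shifted toward
#' smaller size, wider notch, narrower medial condyle), builds femur and
#' tibia meshes from the planted orthonormal fields plus spatially
#' correlated residual noise and a random rigid pose per bone, and
#' generates a matched patient-record table: demographics are drawn
#' pairwise (each MPMS patient jittered from a responder partner,
#' emulating case-control matching, so group comparisons are null);
#' sex is correlated with the size score; KOOS pain is drawn above 75 for
#' R and at or below 75 for MPMS by construction; cartilage grades follow
#' one pooled distribution with identical counts in both groups. The
#' planted per-patient mode scores are returned as ground truth for
#' recovery tests. Fully reproducible under the specification's seed.
#'
#' @param spec a [cohortSpec()].
#' @return list with `femur` and `tibia` (lists of [TriangleMesh-class],
#'   NULL when `spec$meshes` is FALSE), `records` (validated data.frame),
#'   `groundTruth` (patient_id, group, and the three mode scores),
#'   `templates` (the [makeTemplate()] results) and the resolved `spec`.
#' @export
generateCohort <- function(spec = cohortSpec()) {
  stopifnot(inherits(spec, "cohortSpec"))
  oldSeed <- .Random.seed_save()
  on.exit(.Random.seed_restore(oldSeed))
  set.seed(spec$seed)

  nR <- spec$nR; nM <- spec$nMPMS; n <- nR + nM
  group <- c(rep("R", nR), rep("MPMS", nM))
  pid <- sprintf("P%03d", seq_len(n))

  ## --- demographics, matched pairwise between the groups ---
  npair <- min(nR, nM)
  sexR <- rbinom(nR, 1, 1 - spec$femaleProportion)
  sexM <- c(sexR[seq_len(npair)],
            rbinom(max(0, nM - npair), 1, 1 - spec$femaleProportion))
  sex <- c(sexR, sexM)
  baseFor <- function(sx) {
    height <- ifelse(sx == 1, rnorm(length(sx), 179.6, 6.5),
                     rnorm(length(sx), 167.0, 6.0))
    age <- pmin(pmax(rnorm(length(sx), 51.7, 11.0), 18), 70)
    bmi <- pmin(pmax(rnorm(length(sx), 26.3, 3.3), 18), 35)
    cbind(height = height, age = age, bmi = bmi)
  }
  baseR <- baseFor(sexR)
  baseM <- rbind(baseR[seq_len(npair), , drop = FALSE],
                 if (nM > npair) baseFor(sexM[(npair + 1L):nM]))
  jit <- function(m) cbind(height = m[, "height"] + rnorm(nrow(m), 0, 2),
                           age = pmin(pmax(m[, "age"] + rnorm(nrow(m), 0, 3), 18), 70),
                           bmi = pmin(pmax(m[, "bmi"] + rnorm(nrow(m), 0, 0.8), 18), 35))
  demo <- rbind(jit(baseR), jit(baseM))
  height <- round(demo[, "height"], 1)
  age <- round(demo[, "age"], 0)
  bmi0 <- demo[, "bmi"]
  weight <- round(bmi0 * (height / 100)^2, 1)
  bmi <- round(weight / (height / 100)^2, 2)

  ## --- KOOS: pain respects the split at KOOS_SPLIT by construction ---
  pain <- numeric(n)
  pain[group == "R"] <- KOOS_SPLIT + (100 - KOOS_SPLIT) * rbeta(nR, 2, 1.3)
  pain[group == "MPMS"] <- KOOS_SPLIT * rbeta(nM, 5, 2)
  drawSub <- function() pmin(pmax(pain + rnorm(n, 0, 8), 0), 100)
  koos <- cbind(symptoms = drawSub(), pain = pain, adl = drawSub(),
                sport = drawSub(), qol = drawSub())
  koos <- round(koos, 1)
  koosTotal <- round(rowMeans(koos), 1)

  ## --- cartilage: identical grade counts in both groups (matching) ---
  cartProps <- list(
    cart_mfc = c(0.350, 0.388, 0.204, 0.058),
    cart_mtp = c(0.475, 0.400, 0.100, 0.025),
    cart_lfc = c(0.655, 0.317, 0.008, 0.020),
    cart_ltp = c(0.650, 0.317, 0.013, 0.020))
  cart <- lapply(cartProps, function(p) {
    mk <- function(ng) {
      cnt <- floor(p * ng)
      rem <- ng - sum(cnt)
      if (rem > 0) cnt[seq_len(rem)] <- cnt[seq_len(rem)] + 1L
      sample(rep(.cartilageLevels, cnt))
    }
    c(mk(nR), mk(nM))
  })

  ## --- planted mode scores ---
  zsex <- (sex - mean(sex)) / max(sd(sex), 1e-12)
  rho <- spec$sexSizeCor
  # centred group coding: the MPMS-minus-R contrast equals the configured
  # shift while the pooled score mean stays at zero, so the cohort is
  # centred on the template
  shift <- (group == "MPMS") - mean(group == "MPMS")
  aSize <- rho * zsex + sqrt(max(1 - rho^2, 0)) * rnorm(n) +
    shift * spec$shiftSize
  aNotch <- rnorm(n) + shift * spec$shiftNotch
  aCondyle <- rnorm(n) + shift * spec$shiftCondyle

  records <- data.frame(
    patient_id = pid, group = group, sex = sex, age = age, height = height,
    weight = weight, bmi = bmi,
    koos_symptoms = koos[, "symptoms"], koos_pain = koos[, "pain"],
    koos_adl = koos[, "adl"], koos_sport = koos[, "sport"],
    koos_qol = koos[, "qol"], koos_total = koosTotal,
    cart_mfc = cart$cart_mfc, cart_mtp = cart$cart_mtp,
    cart_lfc = cart$cart_lfc, cart_ltp = cart$cart_ltp,
    stringsAsFactors = FALSE)
  records <- validateRecords(records)

  groundTruth <- data.frame(patient_id = pid, group = group,
                            size = aSize, notch = aNotch, condyle = aCondyle)

  gi <- if (spec$meshes) spec$gaugeIters else 0  # gauge needed for meshes only
  tplF <- makeTemplate("femur", resolution = spec$resolution, gaugeIters = gi,
                       params = spec$registration)
  tplT <- makeTemplate("tibia", resolution = spec$resolution, gaugeIters = gi,
                       params = spec$registration)
  femur <- tibia <- NULL
  if (spec$meshes) {
    scores <- cbind(aSize, aNotch, aCondyle)
    coefF <- c(spec$sizeSD, spec$notchSD, spec$condyleSD)
    coefT <- unname(spec$tibiaCoef)
    mkBones <- function(tpl, coef) {
      B <- .noiseBasis(tpl$u, tpl$v)
      # residual noise lives orthogonal to the planted modes: noise along a
      # planted field is indistinguishable from jitter of that mode's score
      B <- B - tpl$fields %*% crossprod(tpl$fields, B)
      B <- .gramSchmidt(B)
      V3 <- nrow(tpl$fields)
      rhoN <- 0.97
      # noiseSD is the RMS 3D displacement per vertex; isotropic components
      sigc <- spec$noiseSD / sqrt(3)
      sdSmooth <- sqrt(0.9 * sigc^2 * V3 /
                         sum(rhoN^(2 * (seq_len(ncol(B)) - 1))))
      sdj <- sdSmooth * rhoN^(seq_len(ncol(B)) - 1)
      base <- .vecShape(tpl$mesh@vertices)
      lapply(seq_len(n), function(i) {
        defo <- base + tpl$fields %*% (coef * scores[i, ]) +
          B %*% (sdj * rnorm(ncol(B))) +
          rnorm(V3, 0, sqrt(0.1) * sigc)
        pose <- .randomRigidPose(spec$poseMaxAngle, spec$poseMaxShift)
        TriangleMesh(applyRigid(.unvecShape(as.numeric(defo)), pose),
                     tpl$mesh@faces,
                     name = sprintf("%s_%s", sub("_template$", "", tpl$mesh@name),
                                    pid[i]))
      })
    }
    femur <- mkBones(tplF, coefF)
    tibia <- mkBones(tplT, coefT)
  }

  list(femur = femur, tibia = tibia, records = records,
       groundTruth = groundTruth,
       templates = list(femur = tplF, tibia = tplT), spec = spec)
}

#' Principal angles between recovered modes and planted fields
#'
#' Compares the leading modes of a fitted shape model against the
#' generator's planted displacement fields on the model's analysis
#' region. Because aligned shapes live in the quotient of coordinate
#' space by rigid motions, both the planted fields (restricted to the
#' region and rotated into the model frame) and the recovered modes are
#' projected orthogonally to the rigid-motion subspace before the angles
#' are computed.
#'
#' @param model a [ShapeModel-class] built on the (possibly cropped)
#'   template.
#' @param template a [makeTemplate()] result.
#' @param mask optional [VertexMask-class] describing the crop the model
#'   was built on (NULL = full template).
#' @param nModes number of leading modes to compare (default 3).
#' @return numeric vector of principal angles in degrees, increasing.
#' @export
plantedSubspaceAngles <- function(model, template, mask = NULL, nModes = 3) {
  tplShape <- CorrespondedShape(meshVertices(template$mesh),
                                meshFaces(template$mesh),
                                template$mesh@name)
  fields <- template$fields
  if (!is.null(mask)) {
    tplShape <- cropRegion(tplShape, mask)
    fields <- fields[rep(mask@include, each = 3L), , drop = FALSE]
  }
  if (nrow(fields) != length(model@mean))
    stop("mask/template do not match the model's vertex count")
  tr <- rigidFit(shapeCoords(tplShape), modelMean(model))
  rot <- function(f) .vecShape(.unvecShape(f) %*% t(tr$R))
  fieldsRot <- apply(fields, 2L, rot)
  refVerts <- applyRigid(shapeCoords(tplShape), tr)
  planted <- qr.Q(qr(.projectOutRigid(fieldsRot, refVerts)))
  rec <- qr.Q(qr(.projectOutRigid(
    model@modes[, seq_len(nModes), drop = FALSE], .unvecShape(model@mean))))
  sv <- svd(crossprod(planted, rec))$d
  sort(acos(pmin(pmax(sv, -1), 1)) * 180 / pi)
}
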