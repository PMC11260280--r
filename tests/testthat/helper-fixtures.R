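## Shared fixtures and independent oracles for the test suite.

# single right-triangle mesh in the z = 0 plane
triMesh <- function() {
  TriangleMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
               rbind(c(1L, 2L, 3L)), name = "tri")
}

# flat rectangular grid patch in the z = zoff plane
planeMesh <- function(n = 5, width = 10, zoff = 0, name = "plane") {
  g <- expand.grid(x = seq(0, width, length.out = n),
                   y = seq(0, width, length.out = n))
  TriangleMesh(cbind(g$x, g$y, zoff), kneeSSM:::.gridFaces(n, n), name = name)
}

# small irregular closed-ish mesh (octahedron)
octaMesh <- function(scale = 1) {
  v <- scale * rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                     c(0, 0, 1), c(0, 0, -1))
  f <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
             c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  TriangleMesh(v, f, name = "octa")
}

# random proper rotation + translation
randomRigid <- function() {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  list(R = diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K),
       t = runif(3, -20, 20))
}

# brute-force point-to-triangle distance oracle (dense barycentric grid,
# refined): independent of the C++ region-partition implementation
bruteClosestDist <- function(p, a, b, c, steps = 400) {
  s <- seq(0, 1, length.out = steps)
  g <- expand.grid(u = s, v = s)
  g <- g[g$u + g$v <= 1, ]
  pts <- outer(1 - g$u - g$v, a) + outer(g$u, b) + outer(g$v, c)
  dim(pts) <- c(nrow(g), 3)
  min(sqrt(rowSums(sweep(pts, 2, p)^2)))
}

# exhaustive pairwise-concordance AUC oracle (ties counted 1/2)
aucOracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# valid minimal patient-record data.frame
recordFixture <- function(n = 6) {
  nR <- ceiling(n / 2); nM <- n - nR
  height <- rep(175, n); bmi <- rep(26.8, n)
  weight <- bmi * (height / 100)^2
  data.frame(
    patient_id = sprintf("P%02d", seq_len(n)),
    group = c(rep("R", nR), rep("MPMS", nM)),
    sex = rep(c(0, 1), length.out = n),
    age = seq(40, 60, length.out = n),
    height = height, weight = weight, bmi = bmi,
    koos_symptoms = c(rep(90, nR), rep(60, nM)),
    koos_pain = c(rep(85, nR), rep(55, nM)),
    koos_adl = c(rep(88, nR), rep(58, nM)),
    koos_sport = c(rep(80, nR), rep(50, nM)),
    koos_qol = c(rep(82, nR), rep(52, nM)),
    koos_total = c(rep(85, nR), rep(55, nM)),
    cart_mfc = rep("0-I", n), cart_mtp = rep("II", n),
    cart_lfc = rep("0-I", n), cart_ltp = rep("0-I", n),
    stringsAsFactors = FALSE)
}

# cached low-resolution templates without gauge iterations (fast)
rawTemplate <- local({
  cache <- list()
  function(bone, resolution = 10) {
    key <- paste(bone, resolution)
    if (is.null(cache[[key]]))
      cache[[key]] <<- makeTemplate(bone, resolution = resolution,
                                    gaugeIters = 0)
    cache[[key]]
  }
})
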