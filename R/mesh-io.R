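## Triangular-mesh readers and writers.
##
## Supported dialects (kept deliberately narrow, and documented):
##   PLY  ascii and binary_little_endian; vertex properties x, y, z
##        (float or double), faces as a list property of vertex indices.
##   STL  ascii and binary; binary coordinates are float32 by the format's
##        definition, so binary STL round-trips only to float32 precision.
##   OBJ  ascii, v/f records only (texture/normal references on f are
##        stripped).
## All coordinates are millimetres; writers record that where the format
## has room for a comment.

.meshFormatFromPath <- function(path, format = NULL) {
  if (!is.null(format)) return(match.arg(tolower(format), c("ply", "stl", "obj")))
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("ply", "stl", "obj"))
    stop("cannot infer mesh format from extension '", ext, "'; pass format=")
  ext
}

#' Read a triangular surface mesh
#'
#' Reads PLY (ascii or binary_little_endian), STL (ascii or binary) or OBJ.
#' The vertex/face order of the file is preserved without reindexing
#' (except STL, which stores triangle soup: identical vertices are welded
#' in order of first appearance). The returned mesh is validated: finite
#' coordinates, in-range and distinct face indices, at least one vertex
#' and face.
#'
#' @param path file to read.
#' @param format one of `"ply"`, `"stl"`, `"obj"`; inferred from the file
#'   extension when omitted.
#' @param name mesh label; defaults to the file base name.
#' @return A [TriangleMesh-class].
#' @export
readMesh <- function(path, format = NULL, name = NULL) {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  format <- .meshFormatFromPath(path, format)
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  out <- switch(format,
    ply = .readPLY(path),
    stl = .readSTL(path),
    obj = .readOBJ(path))
  mesh <- TriangleMesh(out$vertices, out$faces, name = name)
  validObject(mesh)
  mesh
}

#' Write a triangular surface mesh
#'
#' The mesh is validated before writing; serialization is deterministic
#' (the same mesh always produces byte-identical files). ASCII formats
#' print coordinates with 8 decimals (1e-8 mm declared precision); binary
#' PLY stores doubles, binary STL stores float32 as its format requires.
#'
#' @param mesh a valid [TriangleMesh-class].
#' @param path output file.
#' @param format `"ply"`, `"stl"` or `"obj"`; inferred from extension when
#'   omitted.
#' @param binary write the binary flavour (PLY and STL only).
#' @return `path`, invisibly.
#' @export
writeMesh <- function(mesh, path, format = NULL, binary = FALSE) {
  validObject(mesh)
  format <- .meshFormatFromPath(path, format)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path (directory missing): ", dir)
  switch(format,
    ply = .writePLY(mesh, path, binary),
    stl = .writeSTL(mesh, path, binary),
    obj = {
      if (binary) stop("OBJ has no binary flavour")
      .writeOBJ(mesh, path)
    })
  invisible(path)
}

.fmtCoord <- function(x) sprintf("%.8f", x)

## ---- PLY --------------------------------------------------------------

.readPLY <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header is always ASCII lines
  header <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("PLY parse error: end of file inside header")
    header <- c(header, line)
    if (line == "end_header") break
    if (length(header) > 200L) stop("PLY parse error: header not terminated")
  }
  if (header[1L] != "ply") stop("PLY parse error at line 1: missing 'ply' magic")
  fmt <- grep("^format ", header, value = TRUE)
  if (length(fmt) != 1L) stop("PLY parse error: missing format line")
  binary <- grepl("binary_little_endian", fmt)
  if (!binary && !grepl("ascii", fmt))
    stop("PLY parse error: unsupported format '", fmt, "'")

  # element/property layout
  elems <- list(); cur <- NULL
  for (ln in header) {
    tok <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (tok[1L] == "element") {
      cur <- tok[2L]
      elems[[cur]] <- list(n = as.integer(tok[3L]), props = list())
    } else if (tok[1L] == "property" && !is.null(cur)) {
      elems[[cur]]$props[[length(elems[[cur]]$props) + 1L]] <- tok[-1L]
    }
  }
  if (is.null(elems$vertex) || is.null(elems$face))
    stop("PLY parse error: need 'vertex' and 'face' elements")
  vprops <- vapply(elems$vertex$props, function(p) p[length(p)], "")
  if (length(vprops) < 3L || !identical(vprops[1:3], c("x", "y", "z")))
    stop("PLY parse error: first vertex properties must be x, y, z")
  if (length(vprops) > 3L)
    stop("PLY parse error: extra vertex properties not supported")
  vtype <- elems$vertex$props[[1L]][1L]
  nv <- elems$vertex$n; nf <- elems$face$n

  if (binary) {
    sz <- switch(vtype, float = 4L, float32 = 4L, double = 8L, float64 = 8L,
                 stop("PLY parse error: vertex type '", vtype, "'"))
    raw <- readBin(con, "double", n = 3L * nv, size = sz, endian = "little")
    if (length(raw) < 3L * nv)
      stop("PLY parse error: vertex data truncated (expected ", nv,
           " vertices, got ", length(raw) %/% 3L, ")")
    vertices <- matrix(raw, ncol = 3L, byrow = TRUE)
    faces <- matrix(0L, nf, 3L)
    for (i in seq_len(nf)) {
      cnt <- readBin(con, "integer", n = 1L, size = 1L, signed = FALSE)
      if (length(cnt) == 0L)
        stop("PLY parse error: face data truncated at face ", i)
      if (cnt != 3L) stop("PLY parse error: face ", i, " has ", cnt,
                          " vertices; only triangles supported")
      idx <- readBin(con, "integer", n = 3L, size = 4L, endian = "little")
      if (length(idx) < 3L) stop("PLY parse error: face data truncated at face ", i)
      faces[i, ] <- idx + 1L
    }
  } else {
    body <- readLines(con)
    body <- body[nzchar(trimws(body))]
    if (length(body) < nv + nf)
      stop("PLY parse error: body has ", length(body), " lines but header ",
           "declares ", nv, " vertices + ", nf, " faces")
    vl <- body[seq_len(nv)]
    vertices <- matrix(as.numeric(unlist(strsplit(trimws(vl), "\\s+"))),
                       ncol = 3L, byrow = TRUE)
    if (anyNA(vertices)) stop("PLY parse error: non-numeric vertex record")
    fl <- body[nv + seq_len(nf)]
    ftok <- strsplit(trimws(fl), "\\s+")
    faces <- t(vapply(seq_along(ftok), function(i) {
      tk <- as.integer(ftok[[i]])
      if (tk[1L] != 3L) stop("PLY parse error: face ", i, " is not a triangle")
      tk[2:4] + 1L
    }, integer(3L)))
  }
  if (!all(is.finite(vertices)))
    stop("mesh validation error: non-finite vertex coordinate in ", path)
  list(vertices = vertices, faces = faces)
}

.writePLY <- function(mesh, path, binary) {
  v <- mesh@vertices; f <- mesh@faces
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
           "comment units: millimetres",
           sprintf("element vertex %d", nrow(v)),
           "property double x", "property double y", "property double z",
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices",
           "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (binary) {
    writeBin(as.numeric(t(v)), con, size = 8L, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f[i, ] - 1L), con, size = 4L, endian = "little")
    }
  } else {
    writeLines(paste(.fmtCoord(v[, 1L]), .fmtCoord(v[, 2L]), .fmtCoord(v[, 3L])),
               con, sep = "\n")
    writeLines(paste(3L, f[, 1L] - 1L, f[, 2L] - 1L, f[, 3L] - 1L),
               con, sep = "\n")
  }
}

## ---- STL --------------------------------------------------------------

.isBinarySTL <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", n = 84L)
  if (length(head) < 84L) return(FALSE)
  ntri <- readBin(head[81:84], "integer", size = 4L, endian = "little")
  # binary iff the declared triangle count matches the file size
  isTRUE(sz == 84 + 50 * ntri)
}

.readSTL <- function(path) {
  if (.isBinarySTL(path)) .readSTLbinary(path) else .readSTLascii(path)
}

.readSTLascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^\\s*solid", lines[1L]))
    stop("STL parse error at line 1: expected 'solid'")
  vidx <- grep("^\\s*vertex\\s", lines)
  if (length(vidx) == 0L) stop("STL parse error: no vertex records")
  if (length(vidx) %% 3L != 0L)
    stop("STL parse error: vertex count ", length(vidx),
         " is not a multiple of 3 (truncated facet near line ",
         vidx[length(vidx)], ")")
  tok <- strsplit(trimws(lines[vidx]), "\\s+")
  coords <- t(vapply(tok, function(tk) as.numeric(tk[2:4]), numeric(3L)))
  if (anyNA(coords)) stop("STL parse error: non-numeric vertex record")
  .weldTriangleSoup(coords)
}

.readSTLbinary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  ntri <- readBin(con, "integer", size = 4L, endian = "little")
  coords <- matrix(NA_real_, 3L * ntri, 3L)
  for (i in seq_len(ntri)) {
    rec <- readBin(con, "double", n = 12L, size = 4L, endian = "little")
    if (length(rec) < 12L) stop("STL parse error: truncated at facet ", i,
                                " (byte ", 84 + 50 * (i - 1), ")")
    coords[3L * i - 2:0, ] <- matrix(rec[4:12], 3L, 3L, byrow = TRUE)
    readBin(con, "raw", n = 2L)
  }
  .weldTriangleSoup(coords)
}

# STL stores triangle soup; weld identical coordinates, keeping first-seen order
.weldTriangleSoup <- function(coords) {
  key <- paste(sprintf("%.17g", coords[, 1L]), sprintf("%.17g", coords[, 2L]),
               sprintf("%.17g", coords[, 3L]))
  first <- !duplicated(key)
  vertices <- coords[first, , drop = FALSE]
  idx <- match(key, key[first])
  faces <- matrix(idx, ncol = 3L, byrow = TRUE)
  list(vertices = vertices, faces = faces)
}

.writeSTL <- function(mesh, path, binary) {
  v <- mesh@vertices; f <- mesh@faces
  n <- faceNormals(mesh)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw(sprintf("%-80s", "kneeSSM binary STL; units millimetres"))
    writeBin(hdr[1:80], con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(c(n[i, ], t(v[f[i, ], ]))), con, size = 4L,
               endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  } else {
    out <- character(0)
    out <- c(out, sprintf("solid %s", if (nzchar(mesh@name)) mesh@name else "mesh"))
    for (i in seq_len(nrow(f))) {
      out <- c(out,
        sprintf("  facet normal %s %s %s", .fmtCoord(n[i, 1L]),
                .fmtCoord(n[i, 2L]), .fmtCoord(n[i, 3L])),
        "    outer loop",
        sprintf("      vertex %s %s %s", .fmtCoord(v[f[i, ], 1L]),
                .fmtCoord(v[f[i, ], 2L]), .fmtCoord(v[f[i, ], 3L])),
        "    endloop", "  endfacet")
    }
    out <- c(out, sprintf("endsolid %s", if (nzchar(mesh@name)) mesh@name else "mesh"))
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(out, con, sep = "\n")
  }
}

## ---- OBJ --------------------------------------------------------------

.readOBJ <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines)
  fl <- grep("^f\\s", lines)
  if (!length(vl)) stop("OBJ parse error: no 'v' records")
  if (!length(fl)) stop("OBJ parse error: no 'f' records")
  vt <- strsplit(trimws(lines[vl]), "\\s+")
  vertices <- t(vapply(seq_along(vt), function(i) {
    x <- suppressWarnings(as.numeric(vt[[i]][2:4]))
    if (anyNA(x)) stop("OBJ parse error at line ", vl[i], ": bad vertex")
    x
  }, numeric(3L)))
  ft <- strsplit(trimws(lines[fl]), "\\s+")
  faces <- t(vapply(seq_along(ft), function(i) {
    tk <- ft[[i]][-1L]
    if (length(tk) != 3L)
      stop("OBJ parse error at line ", fl[i], ": only triangles supported")
    idx <- suppressWarnings(as.integer(sub("/.*$", "", tk)))
    if (anyNA(idx)) stop("OBJ parse error at line ", fl[i], ": bad face index")
    idx
  }, integer(3L)))
  list(vertices = vertices, faces = faces)
}

.writeOBJ <- function(mesh, path) {
  v <- mesh@vertices; f <- mesh@faces
  out <- c(sprintf("# kneeSSM OBJ; units millimetres; mesh '%s'", mesh@name),
           paste("v", .fmtCoord(v[, 1L]), .fmtCoord(v[, 2L]), .fmtCoord(v[, 3L])),
           paste("f", f[, 1L], f[, 2L], f[, 3L]))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(out, con, sep = "\n")
}
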