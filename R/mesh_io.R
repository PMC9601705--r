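#' Read a triangle mesh from disk
#'
#' Supports STL (binary and ASCII), PLY (ascii and binary_little_endian) and
#' OBJ (`v`/`f` records). STL stores each facet's vertices independently
#' ("facet soup"); after reading an STL the duplicated vertices are welded
#' with [weld_vertices()] at tolerance `weld_tol`. Per-facet normals stored in
#' binary STL are discarded: normals are always recomputed from the vertex
#' winding (see [face_normals()]) so that every format behaves identically.
#'
#' @param path path to the mesh file.
#' @param format one of `"auto"` (default, by file extension), `"stl"`,
#'   `"ply"`, `"obj"`.
#' @param weld_tol welding tolerance applied to STL input (default 1e-6).
#' @return A [triangle_mesh()].
#' @export
read_mesh <- function(path, format = c("auto", "stl", "ply", "obj"),
                      weld_tol = 1e-6) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read mesh: file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("stl", "ply", "obj"))
      stop("cannot infer mesh format from extension '", ext, "'")
    format <- ext
  }
  mesh <- switch(format,
    stl = read_stl(path),
    ply = read_ply(path),
    obj = read_obj(path)
  )
  if (n_faces(mesh) == 0L) stop("mesh has zero faces: ", path)
  if (format == "stl") mesh <- weld_vertices(mesh, tol = weld_tol)
  mesh$provenance <- list(path = path, format = format)
  mesh
}

#' Write a triangle mesh to disk
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path; the format is taken from the extension unless
#'   `format` is given.
#' @param format `"auto"`, `"stl"`, `"ply"` or `"obj"`.
#' @param binary write the binary variant where the format has one
#'   (binary STL, binary_little_endian PLY). OBJ is always text.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "stl", "ply", "obj"),
                       binary = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("stl", "ply", "obj"))
      stop("cannot infer mesh format from extension '", ext, "'")
    format <- ext
  }
  switch(format,
    stl = if (binary) write_stl_binary(mesh, path) else write_stl_ascii(mesh, path),
    ply = write_ply(mesh, path, binary = binary),
    obj = write_obj(mesh, path)
  )
  invisible(path)
}

# ---- STL ---------------------------------------------------------------

stl_is_binary <- function(path) {
  n <- file.size(path)
  if (n < 84) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", 80)
  nfacet <- readBin(con, "integer", 1, size = 4, endian = "little")
  # binary size formula: 84 + 50 bytes per facet
  if (!is.na(nfacet) && nfacet >= 0 && n == 84 + 50 * as.numeric(nfacet))
    return(TRUE)
  !startsWith(tolower(rawToChar(head[1:5])), "solid")
}

read_stl <- function(path) {
  if (stl_is_binary(path)) read_stl_binary(path) else read_stl_ascii(path)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  nfacet <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (is.na(nfacet) || nfacet < 1) stop("binary STL with zero facets: ", path)
  raw <- readBin(con, "raw", 50 * nfacet)
  if (length(raw) < 50 * nfacet) stop("truncated binary STL: ", path)
  m <- matrix(raw, nrow = 50)       # one facet per column
  floats <- readBin(as.vector(m[1:48, ]), "numeric", size = 4,
                    n = 12 * nfacet, endian = "little")
  fl <- matrix(floats, nrow = 12)   # normal(3) + v1 v2 v3 per column
  verts <- matrix(as.vector(fl[4:12, ]), ncol = 3, byrow = TRUE)
  faces <- matrix(seq_len(3 * nfacet), ncol = 3, byrow = TRUE)
  triangle_mesh(verts, faces)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vlines) == 0L || length(vlines) %% 3L != 0L)
    stop("malformed ASCII STL (vertex count not a multiple of 3): ", path)
  nums <- strsplit(trimws(vlines), "\\s+")
  verts <- t(vapply(nums, function(x) as.numeric(x[2:4]), numeric(3)))
  if (anyNA(verts)) stop("non-numeric vertex in ASCII STL: ", path)
  faces <- matrix(seq_len(nrow(verts)), ncol = 3, byrow = TRUE)
  triangle_mesh(verts, faces)
}

write_stl_binary <- function(mesh, path) {
  nf <- n_faces(mesh)
  nrm <- face_normals(mesh)
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(formatC("dentalseg binary STL", width = -80))
  writeBin(header[1:80], con)
  writeBin(as.integer(nf), con, size = 4, endian = "little")
  v <- mesh$vertices
  f <- mesh$faces
  # 12 floats per facet: normal, v1, v2, v3 (row-per-facet, then transpose)
  block <- cbind(nrm, v[f[, 1], , drop = FALSE], v[f[, 2], , drop = FALSE],
                 v[f[, 3], , drop = FALSE])
  payload <- writeBin(as.numeric(t(block)), raw(), size = 4, endian = "little")
  pm <- matrix(raw(1), nrow = 50, ncol = nf)
  pm[1:48, ] <- matrix(payload, nrow = 48)
  writeBin(as.vector(pm), con)
  invisible(path)
}

write_stl_ascii <- function(mesh, path) {
  nrm <- face_normals(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  fmt <- function(m) apply(m, 1, function(r) sprintf("%.9g %.9g %.9g",
                                                     r[1], r[2], r[3]))
  body <- paste0(
    "facet normal ", fmt(nrm), "\n",
    "  outer loop\n",
    "    vertex ", fmt(v[f[, 1], , drop = FALSE]), "\n",
    "    vertex ", fmt(v[f[, 2], , drop = FALSE]), "\n",
    "    vertex ", fmt(v[f[, 3], , drop = FALSE]), "\n",
    "  endloop\n",
    "endfacet"
  )
  writeLines(c("solid dentalseg", body, "endsolid dentalseg"), path)
  invisible(path)
}

# ---- PLY ---------------------------------------------------------------

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_scalar <- function(con, type) {
  sz <- ply_type_size[[type]]
  if (type %in% c("float", "float32", "double", "float64")) {
    readBin(con, "numeric", 1, size = sz, endian = "little")
  } else {
    signed <- !startsWith(type, "u")
    readBin(con, "integer", 1, size = sz, signed = signed || sz >= 4,
            endian = "little")
  }
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, 1)
    if (length(line) == 0L) stop("truncated PLY header: ", path)
    header <- c(header, line)
    if (trimws(line) == "end_header") break
  }
  if (trimws(header[1]) != "ply") stop("not a PLY file: ", path)
  fmt_line <- grep("^format ", header, value = TRUE)[1]
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ", fmt)

  elements <- list(); cur <- NULL
  for (line in header) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$props[[tok[5]]] <- list(list = TRUE, count_type = tok[3],
                                    item_type = tok[4])
      } else {
        cur$props[[tok[3]]] <- list(list = FALSE, type = tok[2])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  ve <- elements[["vertex"]]
  fe <- elements[["face"]]
  if (is.null(ve) || is.null(fe)) stop("PLY lacks vertex/face elements: ", path)

  if (fmt == "ascii") {
    rest <- readLines(con)
    rest <- rest[nzchar(trimws(rest))]
    vl <- rest[seq_len(ve$count)]
    vt <- lapply(strsplit(trimws(vl), "\\s+"), as.numeric)
    pnames <- names(ve$props)
    ix <- match(c("x", "y", "z"), pnames)
    if (anyNA(ix)) stop("PLY vertex element lacks x/y/z: ", path)
    verts <- t(vapply(vt, function(r) r[ix], numeric(3)))
    fl <- rest[ve$count + seq_len(fe$count)]
    ft <- lapply(strsplit(trimws(fl), "\\s+"), as.numeric)
    nvert <- vapply(ft, `[`, numeric(1), 1)
    if (any(nvert != 3))
      stop("unsupported topology: PLY contains non-triangular faces")
    faces <- t(vapply(ft, function(r) r[2:4], numeric(3))) + 1
  } else {
    pnames <- names(ve$props)
    ptypes <- vapply(ve$props, function(p) p$type, character(1))
    ix <- match(c("x", "y", "z"), pnames)
    if (anyNA(ix)) stop("PLY vertex element lacks x/y/z: ", path)
    fp <- fe$props[[1]]
    all_float <- all(ptypes %in% c("float", "float32"))
    if (all_float && fp$count_type %in% c("uchar", "uint8") &&
          fp$item_type %in% c("int", "int32", "uint", "uint32")) {
      # fast path: fixed 4-byte vertex props, (uchar, int32) face lists
      np <- length(ptypes)
      vals <- readBin(con, "numeric", np * ve$count, size = 4,
                      endian = "little")
      vm <- matrix(vals, ncol = np, byrow = TRUE)
      verts <- vm[, ix, drop = FALSE]
      fraw <- readBin(con, "raw", 13 * fe$count)
      fm <- matrix(fraw, nrow = 13)
      if (any(as.integer(fm[1, ]) != 3L))
        stop("unsupported topology: PLY contains non-triangular faces")
      idx <- readBin(as.vector(fm[2:13, ]), "integer", 3 * fe$count,
                     size = 4, endian = "little")
      faces <- matrix(idx, ncol = 3, byrow = TRUE) + 1L
    } else {
      verts <- matrix(0, ve$count, 3)
      for (i in seq_len(ve$count)) {
        row <- vapply(ptypes, function(tp) ply_read_scalar(con, tp),
                      numeric(1))
        verts[i, ] <- row[ix]
      }
      faces <- matrix(0L, fe$count, 3)
      for (i in seq_len(fe$count)) {
        k <- ply_read_scalar(con, fp$count_type)
        if (k != 3)
          stop("unsupported topology: PLY contains non-triangular faces")
        faces[i, ] <- vapply(1:3, function(j)
          as.integer(ply_read_scalar(con, fp$item_type)), integer(1)) + 1L
      }
    }
  }
  triangle_mesh(verts, faces)
}

write_ply <- function(mesh, path, binary = TRUE) {
  nv <- n_vertices(mesh); nf <- n_faces(mesh)
  header <- c(
    "ply",
    if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
    "comment produced by dentalseg",
    sprintf("element vertex %d", nv),
    "property float x", "property float y", "property float z",
    sprintf("element face %d", nf),
    "property list uchar int vertex_indices",
    "end_header"
  )
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(paste0(paste(header, collapse = "\n"), "\n")), con)
    writeBin(as.numeric(t(mesh$vertices)), con, size = 4, endian = "little")
    f0 <- t(mesh$faces) - 1L
    fraw <- lapply(seq_len(nf), function(i) {
      c(writeBin(as.raw(3L), raw()),
        writeBin(as.integer(f0[, i]), raw(), size = 4, endian = "little"))
    })
    writeBin(do.call(c, fraw), con)
  } else {
    vtxt <- apply(mesh$vertices, 1, function(r)
      sprintf("%.9g %.9g %.9g", r[1], r[2], r[3]))
    ftxt <- apply(mesh$faces - 1L, 1, function(r)
      sprintf("3 %d %d %d", r[1], r[2], r[3]))
    writeLines(c(header, vtxt, ftxt), path)
  }
  invisible(path)
}

# ---- OBJ ---------------------------------------------------------------

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^v\\s", lines, value = TRUE)
  flines <- grep("^f\\s", lines, value = TRUE)
  if (length(vlines) == 0L || length(flines) == 0L)
    stop("OBJ lacks v/f records: ", path)
  verts <- t(vapply(strsplit(trimws(vlines), "\\s+"),
                    function(x) as.numeric(x[2:4]), numeric(3)))
  ftok <- strsplit(trimws(flines), "\\s+")
  if (any(lengths(ftok) != 4L))
    stop("unsupported topology: OBJ contains non-triangular faces")
  faces <- t(vapply(ftok, function(x) {
    as.integer(vapply(strsplit(x[2:4], "/"), `[`, character(1), 1))
  }, integer(3)))
  triangle_mesh(verts, faces)
}

write_obj <- function(mesh, path) {
  vtxt <- apply(mesh$vertices, 1, function(r)
    sprintf("v %.9g %.9g %.9g", r[1], r[2], r[3]))
  ftxt <- apply(mesh$faces, 1, function(r)
    sprintf("f %d %d %d", r[1], r[2], r[3]))
  writeLines(c("# produced by dentalseg", vtxt, ftxt), path)
  invisible(path)
}

# ---- label sidecars ----------------------------------------------------

#' Read / write per-face label files
#'
#' Labels are stored as a plain-text sidecar (conventionally
#' `<mesh>.labels`): a one-line header `C=<classes> N=<faces>` followed by
#' one integer label per line. The round-trip is lossless.
#'
#' @param path label file path.
#' @return `read_labels()` returns an integer vector with attributes
#'   `n_classes` and `n_faces`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- regmatches(lines[1],
                    regexec("^C=(\\d+)\\s+N=(\\d+)\\s*$", lines[1]))[[1]]
  if (length(hdr) != 3L) stop("malformed label header: ", lines[1])
  n_classes <- as.integer(hdr[2]); n <- as.integer(hdr[3])
  labels <- suppressWarnings(as.integer(lines[-1][nzchar(trimws(lines[-1]))]))
  if (length(labels) != n || anyNA(labels))
    stop(sprintf("label file body (%d entries) does not match header N=%d",
                 length(labels), n))
  if (min(labels) < 0L || max(labels) >= n_classes)
    stop(sprintf("labels must lie in [0, %d]", n_classes - 1L))
  structure(labels, n_classes = n_classes, n_faces = n)
}

#' @rdname read_labels
#' @param labels integer vector of labels in `[0, n_classes - 1]`.
#' @param n_classes total class count recorded in the header (default 15).
#' @export
write_labels <- function(labels, path, n_classes = 15L) {
  labels <- as.integer(labels)
  validate_labels(labels, n_faces = length(labels), n_classes = n_classes)
  writeLines(c(sprintf("C=%d N=%d", n_classes, length(labels)),
               as.character(labels)), path)
  invisible(path)
}
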