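#' Triangle mesh objects
#'
#' A `triangle_mesh` is an indexed triangular surface: a numeric vertex
#' matrix, an integer face matrix of vertex indices, and optionally one
#' integer class label per face (0 = gingiva, 1..C-1 = teeth).
#'
#' @param vertices numeric matrix, one row per vertex, three columns (x, y, z).
#' @param faces integer matrix, one row per face, three 1-based vertex indices.
#'   Winding defines the outward normal by the right-hand rule.
#' @param face_labels optional integer vector, one label per face, each in
#'   `[0, n_classes - 1]`.
#' @param n_classes number of semantic classes the labels are drawn from
#'   (default 15: gingiva plus 14 teeth).
#' @param provenance optional list recording the source path / format.
#'
#' @return An object of class `triangle_mesh` with elements `vertices`,
#'   `faces`, `face_labels`, `n_classes` and `provenance`.
#' @export
triangle_mesh <- function(vertices, faces, face_labels = NULL,
                          n_classes = 15L, provenance = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("`vertices` must have 3 columns")
  if (ncol(faces) != 3L) stop("`faces` must have 3 columns")
  if (nrow(faces) < 1L) stop("mesh has zero faces")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of range")
  if (any(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
            faces[, 2] == faces[, 3]))
    stop("a face repeats a vertex index")
  if (!is.null(face_labels)) {
    face_labels <- as.integer(face_labels)
    validate_labels(face_labels, n_faces = nrow(faces), n_classes = n_classes)
  }
  structure(
    list(vertices = vertices, faces = faces, face_labels = face_labels,
         n_classes = as.integer(n_classes), provenance = provenance),
    class = "triangle_mesh"
  )
}

validate_labels <- function(labels, n_faces, n_classes) {
  if (length(labels) != n_faces)
    stop(sprintf("label count (%d) does not match face count (%d)",
                 length(labels), n_faces))
  if (anyNA(labels)) stop("labels contain NA")
  if (min(labels) < 0L || max(labels) >= n_classes)
    stop(sprintf("labels must lie in [0, %d]", n_classes - 1L))
  invisible(labels)
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces", n_vertices(x), n_faces(x)))
  if (!is.null(x$face_labels))
    cat(sprintf(", %d label classes present (C = %d)",
                length(unique(x$face_labels)), x$n_classes))
  cat("\n")
  if (!is.null(x$provenance$path))
    cat(sprintf("  source: %s [%s]\n", x$provenance$path,
                x$provenance$format %||% "?"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname triangle_mesh
#' @param mesh a `triangle_mesh`.
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

#' @rdname triangle_mesh
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' Attach per-face labels to a mesh
#'
#' @param mesh a `triangle_mesh`.
#' @param labels integer vector of per-face labels in `[0, n_classes - 1]`.
#' @param n_classes class count; defaults to the mesh's current value.
#' @return The mesh with `face_labels` set.
#' @export
attach_labels <- function(mesh, labels, n_classes = mesh$n_classes) {
  labels <- as.integer(labels)
  validate_labels(labels, n_faces(mesh), n_classes)
  mesh$face_labels <- labels
  mesh$n_classes <- as.integer(n_classes)
  mesh
}

#' Weld coincident vertices
#'
#' Merges vertices whose coordinates agree within `tol` on every axis and
#' re-indexes the faces. The face count never changes; faces that become
#' degenerate (a repeated vertex index after merging) are recorded in the
#' `"degenerate_faces"` attribute of the result rather than dropped.
#'
#' Merging uses staggered uniform grids (cell size `2 * tol`, offsets 0 and
#' `tol` per axis) with union-find, so any two vertices within `tol` per axis
#' are guaranteed to land in a shared cell of at least one grid.
#'
#' @param mesh a `triangle_mesh`.
#' @param tol non-negative per-axis merge tolerance, in the mesh's length
#'   units. The default 1e-6 sits below scanner precision but above float32
#'   storage noise.
#' @return A welded `triangle_mesh`.
#' @export
weld_vertices <- function(mesh, tol = 1e-6) {
  if (tol < 0) stop("`tol` must be non-negative")
  v <- mesh$vertices
  nv <- nrow(v)
  parent <- seq_len(nv)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  link <- function(i, j) {
    ri <- find_root(i); rj <- find_root(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  merge_by_key <- function(key) {
    first_idx <- match(key, key)   # index of first occurrence of each key
    dup <- which(first_idx != seq_along(key))
    for (i in dup) link(first_idx[i], i)
  }
  if (tol == 0) {
    key <- paste(v[, 1], v[, 2], v[, 3])
    merge_by_key(key)
  } else {
    cell <- 2 * tol
    for (ox in c(0, tol)) for (oy in c(0, tol)) for (oz in c(0, tol)) {
      key <- paste(floor((v[, 1] + ox) / cell),
                   floor((v[, 2] + oy) / cell),
                   floor((v[, 3] + oz) / cell))
      merge_by_key(key)
    }
  }
  root <- vapply(seq_len(nv), find_root, integer(1))
  keep <- sort(unique(root))
  new_id <- integer(nv)
  new_id[keep] <- seq_along(keep)
  map <- new_id[root]
  new_v <- v[keep, , drop = FALSE]
  new_f <- matrix(map[mesh$faces], ncol = 3)
  degenerate <- which(new_f[, 1] == new_f[, 2] | new_f[, 1] == new_f[, 3] |
                        new_f[, 2] == new_f[, 3])
  out <- structure(
    list(vertices = new_v, faces = new_f, face_labels = mesh$face_labels,
         n_classes = mesh$n_classes, provenance = mesh$provenance),
    class = "triangle_mesh"
  )
  attr(out, "degenerate_faces") <- degenerate
  out
}
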