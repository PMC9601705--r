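#' Per-face centroids
#'
#' The centroid of face *i* is the arithmetic mean of its three vertices.
#' Unlike vertices, centroids map one-to-one onto faces, which is why they
#' guide the per-face segmentation.
#'
#' @param mesh a [triangle_mesh()].
#' @return numeric matrix, one row per face (x, y, z).
#' @export
face_centroids <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
     v[f[, 3], , drop = FALSE]) / 3
}

#' Per-face unit normals
#'
#' Row *i* is the normalized cross product `(v2 - v1) x (v3 - v1)`, so the
#' vertex winding defines the outward direction by the right-hand rule.
#' Zero-area faces get the zero vector; their indices are returned in the
#' `"degenerate_faces"` attribute rather than raising an error.
#'
#' @param mesh a [triangle_mesh()].
#' @return numeric matrix, one unit normal per face, with attribute
#'   `degenerate_faces`.
#' @export
face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2))
  degenerate <- which(len < 1e-12)
  len[len < 1e-12] <- 1
  out <- nrm / len
  out[degenerate, ] <- 0
  attr(out, "degenerate_faces") <- degenerate
  out
}

#' Assemble the per-face feature matrix
#'
#' Builds the N x 15 network input: for each face, the nine vertex
#' coordinates, the centroid (3) and the unit normal (3). With
#' `center = TRUE` (the default for training) the mean centroid is
#' subtracted from all coordinate columns — vertices and centroids — so the
#' features are translation-invariant; normals are untouched.
#'
#' @param mesh a [triangle_mesh()].
#' @param center subtract the mean centroid from coordinate columns.
#' @return A `face_features` object: list with `values` (N x 15),
#'   `centroids` (N x 3, same centering), `normals` (N x 3),
#'   `degenerate_faces`, `labels` (or NULL) and `n_classes`.
#' @export
assemble_features <- function(mesh, center = TRUE) {
  if (n_faces(mesh) < 1L) stop("cannot assemble features of an empty mesh")
  v <- mesh$vertices
  f <- mesh$faces
  cen <- face_centroids(mesh)
  nrm <- face_normals(mesh)
  vals <- cbind(v[f[, 1], , drop = FALSE], v[f[, 2], , drop = FALSE],
                v[f[, 3], , drop = FALSE], cen, nrm)
  if (center) {
    mu <- colMeans(cen)
    vals[, 1:12] <- vals[, 1:12] - matrix(mu, nrow(vals), 12, byrow = TRUE)
    cen <- cen - matrix(mu, nrow(cen), 3, byrow = TRUE)
  }
  dimnames(vals) <- NULL
  structure(
    list(values = vals, centroids = cen,
         normals = matrix(as.numeric(nrm), nrow(nrm), 3),
         degenerate_faces = attr(nrm, "degenerate_faces"),
         labels = mesh$face_labels, n_classes = mesh$n_classes),
    class = "face_features"
  )
}

#' @export
print.face_features <- function(x, ...) {
  cat(sprintf("face_features: %d faces x %d columns%s\n", nrow(x$values),
              ncol(x$values),
              if (is.null(x$labels)) "" else " (labeled)"))
  invisible(x)
}

#' Decimate a mesh by quadric edge collapse
#'
#' Reduces the face count to approximately `target_faces` using
#' Garland-Heckbert quadric error metrics. If the mesh carries labels they
#' are transferred to each output face from the input face whose centroid is
#' nearest to the output face's centroid.
#'
#' @param mesh a [triangle_mesh()].
#' @param target_faces desired face count (>= 4). A target at or above the
#'   current face count is a no-op with a warning.
#' @return The decimated `triangle_mesh`.
#' @export
decimate <- function(mesh, target_faces) {
  target_faces <- as.integer(target_faces)
  if (target_faces < 4L) stop("target_faces must be at least 4")
  if (target_faces >= n_faces(mesh)) {
    if (target_faces > n_faces(mesh))
      warning("target_faces exceeds current face count; mesh unchanged")
    return(mesh)
  }
  res <- cpp_decimate_qem(mesh$vertices, mesh$faces, target_faces)
  out <- triangle_mesh(res$vertices, res$faces, n_classes = mesh$n_classes,
                       provenance = mesh$provenance)
  if (!is.null(mesh$face_labels)) {
    old_cen <- face_centroids(mesh)
    new_cen <- face_centroids(out)
    nearest <- cpp_knn_query(new_cen, old_cen, 1L)[, 1]
    out$face_labels <- mesh$face_labels[nearest]
  }
  out
}

#' Randomly augment a labeled mesh
#'
#' Applies the three training-time augmentations: a random translation along
#' each axis, a random isotropic rescaling, and random removal of a small
#' fraction of faces (labels follow the surviving faces). The output is
#' fully determined by `seed`.
#'
#' @param mesh a [triangle_mesh()].
#' @param seed integer seed controlling all randomness.
#' @param translate half-width of the per-axis uniform translation (length
#'   units; default 10).
#' @param scale length-2 numeric, uniform isotropic scale range
#'   (default `c(0.8, 1.2)`).
#' @param remove_frac fraction of faces to remove uniformly at random
#'   (default 0.01; must be < 1).
#' @return The augmented `triangle_mesh`.
#' @export
augment <- function(mesh, seed, translate = 10, scale = c(0.8, 1.2),
                    remove_frac = 0.01) {
  if (remove_frac >= 1) stop("remove_frac must be < 1")
  if (remove_frac < 0) stop("remove_frac must be non-negative")
  with_seed(seed, {
    v <- mesh$vertices
    s <- stats::runif(1, scale[1], scale[2])
    tr <- stats::runif(3, -translate, translate)
    v <- v * s + matrix(tr, nrow(v), 3, byrow = TRUE)
    f <- mesh$faces
    labels <- mesh$face_labels
    n_drop <- floor(remove_frac * nrow(f))
    if (n_drop > 0) {
      drop <- sample.int(nrow(f), n_drop)
      f <- f[-drop, , drop = FALSE]
      if (!is.null(labels)) labels <- labels[-drop]
    }
    # drop vertices orphaned by face removal and re-index
    used <- sort(unique(as.vector(f)))
    remap <- integer(nrow(v))
    remap[used] <- seq_along(used)
    triangle_mesh(v[used, , drop = FALSE], matrix(remap[f], ncol = 3),
                  face_labels = labels, n_classes = mesh$n_classes,
                  provenance = mesh$provenance)
  })
}

# evaluate `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' K-nearest-neighbour face index
#'
#' For each face, the indices of its `K` nearest faces by centroid Euclidean
#' distance, self included (a face is distance 0 from itself, so column 1 is
#' always the face's own index). Exact brute-force search; ties broken by
#' smaller index; distances non-decreasing along each row.
#'
#' @param centroids numeric N x 3 matrix of face centroids.
#' @param K neighbourhood size, `1 <= K <= N`.
#' @return integer N x K matrix of 1-based face indices.
#' @export
knn_indices <- function(centroids, K) {
  centroids <- as.matrix(centroids)
  if (K > nrow(centroids))
    stop(sprintf("K (%d) exceeds the number of faces (%d)",
                 K, nrow(centroids)))
  cpp_knn_query(centroids, centroids, as.integer(K))
}
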