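test_that("binary STL facet soup is read and welded into an indexed mesh", {
  tet <- tetrahedron_mesh()
  facets <- lapply(seq_len(n_faces(tet)), function(i)
    tet$vertices[tet$faces[i, ], ])
  path <- withr::local_tempfile(fileext = ".stl")
  write_binary_stl_soup(facets, path)
  mesh <- read_mesh(path)
  expect_equal(n_vertices(mesh), 4L)
  expect_equal(n_faces(mesh), 4L)
})

test_that("ASCII OBJ single triangle parses with the right-hand-rule normal", {
  path <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1 2 3"), path)
  mesh <- read_mesh(path)
  expect_equal(n_vertices(mesh), 3L)
  expect_equal(n_faces(mesh), 1L)
  expect_equal(as.numeric(face_normals(mesh)), c(0, 0, 1))
})

test_that("unreadable, empty and non-triangular inputs raise clear errors", {
  expect_error(read_mesh("no/such/file.stl"), "not found")
  ply <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0",
               "element vertex 4",
               "property float x", "property float y", "property float z",
               "element face 1", "property list uchar int vertex_indices",
               "end_header",
               "0 0 0", "1 0 0", "1 1 0", "0 1 0",
               "4 0 1 2 3"), ply)
  expect_error(read_mesh(ply), "non-triangular")
  obj <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0", "f 1 2 3 4"), obj)
  expect_error(read_mesh(obj), "non-triangular")
})

test_that("write/read round-trips preserve geometry in every format", {
  mesh <- small_arch(200, seed = 4)
  # indexed formats: exact identity up to storage precision
  for (spec in list(list(ext = ".ply", binary = TRUE, tol = 1e-4),
                    list(ext = ".ply", binary = FALSE, tol = 1e-6),
                    list(ext = ".obj", binary = FALSE, tol = 1e-6))) {
    path <- withr::local_tempfile(fileext = spec$ext)
    write_mesh(mesh, path, binary = spec$binary)
    back <- read_mesh(path)
    expect_equal(back$faces, mesh$faces,
                 label = paste("faces", spec$ext, spec$binary))
    expect_lt(max(abs(back$vertices - mesh$vertices)), spec$tol)
  }
  # STL stores a facet soup; faces keep their order and per-face geometry
  for (binary in c(TRUE, FALSE)) {
    path <- withr::local_tempfile(fileext = ".stl")
    write_mesh(mesh, path, binary = binary)
    back <- read_mesh(path)
    expect_equal(n_faces(back), n_faces(mesh))
    orig <- cbind(mesh$vertices[mesh$faces[, 1], ],
                  mesh$vertices[mesh$faces[, 2], ],
                  mesh$vertices[mesh$faces[, 3], ])
    got <- cbind(back$vertices[back$faces[, 1], ],
                 back$vertices[back$faces[, 2], ],
                 back$vertices[back$faces[, 3], ])
    expect_lt(max(abs(orig - got)), 1e-4)
  }
})

test_that("welding merges coincident vertices without changing faces", {
  # two triangles sharing an edge, stored as 6 independent vertices
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
             c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  soup <- triangle_mesh(v, rbind(1:3, 4:6))
  welded <- weld_vertices(soup, tol = 1e-6)
  expect_equal(n_vertices(welded), 4L)
  expect_equal(n_faces(welded), 2L)
  # tol = 0 still merges exactly equal coordinates
  expect_equal(n_vertices(weld_vertices(soup, tol = 0)), 4L)
})

test_that("welding of jittered duplicates matches a brute-force oracle", {
  set.seed(31)
  base <- matrix(runif(30, 0, 10), 10, 3)
  dup_of <- sample.int(10, 14, replace = TRUE)
  jitter <- matrix(rnorm(14 * 3, sd = 1e-9), 14, 3)
  v <- rbind(base, base[dup_of, ] + jitter)
  f <- matrix(sample.int(24, 24), ncol = 3)
  soup <- triangle_mesh(v, f)
  welded <- weld_vertices(soup, tol = 1e-6)
  # oracle: connected components of the "within tol per axis" relation
  n <- nrow(v)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    if (all(abs(v[i, ] - v[j, ]) <= 1e-6)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  expect_equal(n_vertices(welded), length(unique(vapply(seq_len(n), find, 1L))))
  expect_equal(n_faces(welded), n_faces(soup))
  # face centroids move by at most tol * sqrt(3)
  expect_lt(max(abs(face_centroids(welded) - face_centroids(soup))),
            1e-6 * sqrt(3))
})

test_that("label files round-trip losslessly and validate their inputs", {
  path <- withr::local_tempfile(fileext = ".labels")
  write_labels(c(0L, 0L, 1L, 14L), path, n_classes = 15L)
  back <- read_labels(path)
  expect_equal(as.integer(back), c(0L, 0L, 1L, 14L))
  expect_equal(attr(back, "n_classes"), 15L)

  expect_error(write_labels(c(0L, 15L), path, n_classes = 15L), "\\[0, 14\\]")
  expect_error(write_labels(c(0L, -1L), path, n_classes = 15L), "\\[0, 14\\]")

  set.seed(8)
  big <- sample(0:14, 10000, replace = TRUE)
  write_labels(big, path, n_classes = 15L)
  expect_identical(as.integer(read_labels(path)), big)
})

test_that("attaching labels validates length and range", {
  tet <- tetrahedron_mesh()
  expect_error(attach_labels(tet, c(0L, 1L), n_classes = 15L),
               "does not match face count")
  expect_error(attach_labels(tet, c(0L, 1L, 2L, 15L), n_classes = 15L),
               "\\[0, 14\\]")
  ok <- attach_labels(tet, c(0L, 1L, 2L, 14L), n_classes = 15L)
  expect_equal(ok$face_labels, c(0L, 1L, 2L, 14L))
})
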