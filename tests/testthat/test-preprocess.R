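test_that("face centroids are the vertex means", {
  m <- triangle_mesh(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0)),
                     matrix(1:3, 1))
  expect_equal(as.numeric(face_centroids(m)), c(1, 1, 0))

  set.seed(10)
  v <- matrix(rnorm(1500), 500, 3)
  f <- matrix(sample.int(500, 3 * 100), ncol = 3)
  ok <- f[, 1] != f[, 2] & f[, 1] != f[, 3] & f[, 2] != f[, 3]
  mesh <- triangle_mesh(v, f[ok, ])
  cen <- face_centroids(mesh)
  oracle <- t(apply(mesh$faces, 1, function(r) colMeans(v[r, ])))
  expect_equal(cen, oracle, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("face normals follow the right-hand rule and flag degenerates", {
  m <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                     matrix(1:3, 1))
  expect_equal(as.numeric(face_normals(m)), c(0, 0, 1))
  flipped <- triangle_mesh(m$vertices, matrix(c(1, 3, 2), 1))
  expect_equal(as.numeric(face_normals(flipped)), c(0, 0, -1))

  set.seed(11)
  v <- matrix(rnorm(900), 300, 3)
  f <- matrix(sample.int(300, 3 * 80), ncol = 3)
  ok <- f[, 1] != f[, 2] & f[, 1] != f[, 3] & f[, 2] != f[, 3]
  mesh <- triangle_mesh(v, f[ok, ])
  nrm <- face_normals(mesh)
  expect_true(all(abs(sqrt(rowSums(nrm^2)) - 1) < 1e-6))
  e1 <- v[mesh$faces[, 2], ] - v[mesh$faces[, 1], ]
  e2 <- v[mesh$faces[, 3], ] - v[mesh$faces[, 1], ]
  expect_lt(max(abs(rowSums(nrm * e1))), 1e-6)
  expect_lt(max(abs(rowSums(nrm * e2))), 1e-6)

  # a zero-area face gets a zero normal and is reported, not fatal
  deg <- triangle_mesh(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2), c(1, 0, 0)),
                       rbind(c(1, 2, 3), c(1, 4, 2)))
  nd <- face_normals(deg)
  expect_equal(attr(nd, "degenerate_faces"), 1L)
  expect_equal(as.numeric(nd[1, ]), c(0, 0, 0))
})

test_that("assemble_features builds the N x 15 layout with optional centering", {
  m <- triangle_mesh(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0)),
                     matrix(1:3, 1))
  ff <- assemble_features(m, center = FALSE)
  expect_equal(as.numeric(ff$values),
               c(0, 0, 0, 3, 0, 0, 0, 3, 0, 1, 1, 0, 0, 0, 1))

  arch <- small_arch(250, seed = 6)
  fc <- assemble_features(arch, center = TRUE)
  expect_lt(max(abs(colMeans(fc$centroids))), 1e-9)
  expect_lt(max(abs(colMeans(fc$values[, 10:12]))), 1e-9)
  # centroid columns equal the mean of the three vertex triples
  mean_v <- (fc$values[, 1:3] + fc$values[, 4:6] + fc$values[, 7:9]) / 3
  expect_lt(max(abs(mean_v - fc$values[, 10:12])), 1e-9)

  shifted <- arch
  shifted$vertices <- shifted$vertices +
    matrix(c(5, 5, 5), n_vertices(arch), 3, byrow = TRUE)
  fs <- assemble_features(shifted, center = TRUE)
  expect_equal(fs$values, fc$values, tolerance = 1e-9)
})

test_that("normals rotate with the mesh and ignore translation", {
  arch <- small_arch(250, seed = 6)
  theta <- 0.71
  R <- rbind(c(cos(theta), -sin(theta), 0),
             c(sin(theta), cos(theta), 0),
             c(0, 0, 1))
  rot <- arch
  rot$vertices <- arch$vertices %*% t(R)
  expect_lt(max(abs(face_normals(rot) - face_normals(arch) %*% t(R))), 1e-5)
  shifted <- arch
  shifted$vertices <- arch$vertices + 3.3
  expect_equal(face_normals(shifted), face_normals(arch), tolerance = 1e-9)
})

test_that("quadric decimation hits the target band and transfers labels", {
  ico <- icosphere(3)
  expect_equal(n_faces(ico), 1280L)
  dec <- decimate(ico, 320)
  expect_gte(n_faces(dec), 314L)
  expect_lte(n_faces(dec), 327L)

  # no-op when the target equals or exceeds the face count
  expect_identical(decimate(ico, n_faces(ico)), ico)
  expect_warning(out <- decimate(ico, 2000), "exceeds")
  expect_identical(out, ico)

  arch <- small_arch(2000, seed = 9)
  dec2 <- decimate(arch, 1000)
  expect_true(all(dec2$face_labels %in% unique(arch$face_labels)))
  # classes occupying >= 2% of input faces survive decimation
  tab <- table(arch$face_labels) / n_faces(arch)
  common <- as.integer(names(tab)[tab >= 0.02])
  expect_true(all(common %in% dec2$face_labels))
})

test_that("augmentation is seeded, label-preserving and isometric when pure translation", {
  arch <- small_arch(300, seed = 2)
  same <- augment(arch, seed = 5, translate = 0, scale = c(1, 1),
                  remove_frac = 0)
  expect_equal(same$vertices, arch$vertices, tolerance = 1e-12)
  expect_equal(same$faces, arch$faces)
  expect_equal(same$face_labels, arch$face_labels)

  tr <- augment(arch, seed = 5, translate = 10, scale = c(1, 1),
                remove_frac = 0)
  d0 <- dist(face_centroids(arch)[1:50, ])
  d1 <- dist(face_centroids(tr)[1:50, ])
  expect_lt(max(abs(d0 - d1)), 1e-6)

  a1 <- augment(arch, seed = 7)
  a2 <- augment(arch, seed = 7)
  expect_equal(a1$vertices, a2$vertices)

  big <- small_arch(1000, seed = 3)
  rem <- augment(big, seed = 1, translate = 0, scale = c(1, 1),
                 remove_frac = 0.01)
  expect_equal(n_faces(rem), 990L)
  expect_true(all(rem$face_labels %in% 0:14))
  expect_error(augment(big, seed = 1, remove_frac = 1), "< 1")
})

test_that("knn_indices is exact and self-inclusive", {
  pts <- cbind(c(0, 1, 10), 0, 0)
  nb <- knn_indices(pts, 2)
  expect_equal(nb, rbind(c(1L, 2L), c(2L, 1L), c(3L, 2L)))

  set.seed(12)
  x <- matrix(rnorm(900), 300, 3)
  expect_equal(knn_indices(x, 1)[, 1], 1:300)

  nb20 <- knn_indices(x, 20)
  d2 <- as.matrix(dist(x))^2
  for (i in c(1, 57, 123, 300)) {
    ord <- order(d2[i, ], seq_len(300))[1:20]
    expect_equal(nb20[i, ], ord)
  }
  expect_error(knn_indices(x, 301), "exceeds")
})
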