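test_that("centroid neighbourhood encoding matches hand geometry and an oracle", {
  # two points: self slot and a 3-4-5 pair
  cen <- rbind(c(0, 0, 0), c(3, 4, 0))
  nbr <- knn_indices(cen, 2)
  enc <- encode_centroid_geometry(cen, nbr)
  expect_equal(dim(enc), c(2L, 2L, 10L))
  # k = self: (pi, pi, 0, 0)
  expect_equal(as.numeric(enc[1, 1, ]), c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0))
  # neighbour slot of face 1 is face 2: relative (-3,-4,0), distance 5
  expect_equal(as.numeric(enc[1, 2, ]), c(0, 0, 0, 3, 4, 0, -3, -4, 0, 5))

  set.seed(14)
  cen <- matrix(rnorm(80 * 3), 80, 3)
  nbr <- knn_indices(cen, 7)
  enc <- encode_centroid_geometry(cen, nbr)
  for (i in c(1, 40, 80)) for (k in c(1, 4, 7)) {
    pi_ <- cen[i, ]; pik <- cen[nbr[i, k], ]
    expect_equal(as.numeric(enc[i, k, ]),
                 c(pi_, pik, pi_ - pik, sqrt(sum((pi_ - pik)^2))),
                 tolerance = 1e-12)
  }
})

test_that("normal neighbourhood encoding carries differences and cosines", {
  nrm <- rbind(c(0, 0, 1), c(0, 0, -1))
  nbr <- matrix(c(1L, 2L, 2L, 1L), 2, 2)
  enc <- encode_normal_geometry(nrm, nbr)
  # identical self-pair: difference 0, cosine 1
  expect_equal(as.numeric(enc[1, 1, ]), c(0, 0, 1, 0, 0, 1, 0, 0, 0, 1))
  # antipodal pair: difference (0,0,2), cosine -1
  expect_equal(as.numeric(enc[1, 2, ]), c(0, 0, 1, 0, 0, -1, 0, 0, 2, -1))

  nrm <- random_unit_normals(60, seed = 15)
  nbr <- knn_indices(nrm, 5)
  enc <- encode_normal_geometry(nrm, nbr)
  for (i in c(2, 30, 60)) for (k in c(1, 3, 5)) {
    expect_equal(enc[i, k, 10], sum(nrm[i, ] * nrm[nbr[i, k], ]),
                 tolerance = 1e-6)
  }
  # degenerate zero normal yields cosine 0
  nrm[3, ] <- 0
  enc0 <- encode_normal_geometry(nrm, nbr)
  expect_equal(enc0[3, 1, 10], 0)
})

test_that("ECA kernel sizes follow the adaptive odd rule", {
  expect_equal(eca_kernel_size(2), 1L)
  expect_equal(eca_kernel_size(256), 5L)   # t = 4.5 -> 5
  ks <- vapply(2:4096, eca_kernel_size, integer(1))
  expect_true(all(ks %% 2 == 1))
  expect_true(all(ks >= 1))
  expect_true(all(diff(ks) >= 0))
})

test_that("ECA with zero conv weights halves the input and ignores face order", {
  ps <- dentalseg:::param_store()
  g <- dentalseg:::ad_graph()
  set.seed(16)
  x <- matrix(rnorm(40 * 8), 40, 8)
  xn <- dentalseg:::ad_const(g, x)
  out <- dentalseg:::ad_eca(g, ps, "eca", xn)
  # force the conv kernel to zero: sigmoid(0) = 0.5 per channel
  ps$params[["eca.conv"]]$value[] <- 0
  g2 <- dentalseg:::ad_graph()
  out2 <- dentalseg:::ad_eca(g2, ps, "eca", dentalseg:::ad_const(g2, x))
  expect_equal(out2$value, x / 2, tolerance = 1e-12)

  # loop oracle: pool -> conv -> sigmoid -> scale
  ps$params[["eca.conv"]]$value[] <- c(0.3, -0.2, 0.5)
  g3 <- dentalseg:::ad_graph()
  out3 <- dentalseg:::ad_eca(g3, ps, "eca", dentalseg:::ad_const(g3, x))
  d <- colMeans(x)
  k <- 3; half <- 1
  pad <- c(0, d, 0)
  conv <- vapply(seq_along(d), function(c0)
    sum(c(0.3, -0.2, 0.5) * pad[c0:(c0 + k - 1)]), numeric(1))
  w <- 1 / (1 + exp(-conv))
  oracle <- x * matrix(w, nrow(x), ncol(x), byrow = TRUE)
  expect_equal(out3$value, oracle, tolerance = 1e-12)

  # permuting faces leaves the channel weights unchanged
  perm <- sample(40)
  g4 <- dentalseg:::ad_graph()
  out4 <- dentalseg:::ad_eca(g4, ps, "eca", dentalseg:::ad_const(g4, x[perm, ]))
  expect_equal(out4$value, oracle[perm, ], tolerance = 1e-12)
})

test_that("grouped softmax aggregation matches a loop oracle and its edge cases", {
  set.seed(17)
  N <- 12; K <- 5; D <- 4
  x <- matrix(rnorm(N * K * D), N * K, D)
  g <- dentalseg:::ad_graph()
  sm <- dentalseg:::ad_group_softmax(g, dentalseg:::ad_const(g, x), N, K)
  agg <- dentalseg:::ad_group_rowsum(
    g, dentalseg:::ad_mul(g, dentalseg:::ad_const(g, x), sm), N, K)
  oracle <- matrix(0, N, D)
  for (i in seq_len(N)) for (d in seq_len(D)) {
    rows <- (i - 1) * K + seq_len(K)
    s <- exp(x[rows, d]); s <- s / sum(s)
    oracle[i, d] <- sum(x[rows, d] * s)
  }
  expect_equal(agg$value, oracle, tolerance = 1e-10)

  # K = 1: softmax weight 1, aggregation returns the single slot
  g1 <- dentalseg:::ad_graph()
  sm1 <- dentalseg:::ad_group_softmax(g1, dentalseg:::ad_const(g1, x), N * K, 1)
  expect_true(all(sm1$value == 1))

  # identical slots across K: aggregation equals that feature
  xid <- x[rep(seq(1, N * K, by = K), each = K), ]
  g2 <- dentalseg:::ad_graph()
  sm2 <- dentalseg:::ad_group_softmax(g2, dentalseg:::ad_const(g2, xid), N, K)
  agg2 <- dentalseg:::ad_group_rowsum(
    g2, dentalseg:::ad_mul(g2, dentalseg:::ad_const(g2, xid), sm2), N, K)
  expect_equal(agg2$value, xid[seq(1, N * K, by = K), ], tolerance = 1e-10)
})

test_that("T-Net starts at the identity and is permutation-invariant", {
  cfg <- tiny_config()
  net <- init_network(cfg)
  set.seed(18)
  x <- matrix(rnorm(25 * 15), 25, 15)
  # with the final FC zeroed the transform is exactly the identity
  ps2 <- dentalseg:::param_store()
  g0 <- dentalseg:::ad_graph()
  dentalseg:::ad_tnet(g0, ps2, dentalseg:::ad_const(g0, x), training = FALSE)
  ps2$params[["tnet.fc3.W"]]$value[] <- 0
  ps2$params[["tnet.fc3.b"]]$value[] <- 0
  g <- dentalseg:::ad_graph()
  tn <- dentalseg:::ad_tnet(g, ps2, dentalseg:::ad_const(g, x),
                            training = FALSE)
  expect_equal(dim(tn$transform), c(15L, 15L))
  expect_equal(tn$transform, diag(15))
  expect_equal(tn$aligned$value, x, tolerance = 1e-12)

  # after perturbing the final FC the transform is shared and equivariant
  ps2$params[["tnet.fc3.W"]]$value[] <-
    rnorm(length(ps2$params[["tnet.fc3.W"]]$value), sd = 0.01)
  g3 <- dentalseg:::ad_graph()
  tn3 <- dentalseg:::ad_tnet(g3, ps2, dentalseg:::ad_const(g3, x),
                             training = FALSE)
  perm <- sample(25)
  g4 <- dentalseg:::ad_graph()
  tn4 <- dentalseg:::ad_tnet(g4, ps2, dentalseg:::ad_const(g4, x[perm, ]),
                             training = FALSE)
  expect_equal(tn4$transform, tn3$transform, tolerance = 1e-10)
  expect_equal(tn4$aligned$value, tn3$aligned$value[perm, ], tolerance = 1e-10)
})

test_that("MGFL stages emit the configured widths at paper defaults", {
  cfg <- network_config(seed = 2L)    # full 128/512 widths
  net <- init_network(cfg)
  set.seed(19)
  N <- 30
  feats <- list(values = matrix(rnorm(N * 15), N, 15),
                centroids = matrix(rnorm(N * 3), N, 3),
                normals = random_unit_normals(N, seed = 20))
  out <- dentalseg:::nf_forward(net, feats, training = FALSE)
  expect_equal(dim(out$s1$value), c(N, 128L))
  expect_equal(dim(out$s2$value), c(N, 512L))
  expect_equal(dim(out$transform), c(15L, 15L))
  expect_equal(dim(out$probs$value), c(N, 15L))
  expect_lt(max(abs(rowSums(out$probs$value) - 1)), 1e-5)
})

test_that("residual shortcut carries the block when the main path is zeroed", {
  cfg <- tiny_config()
  net <- init_network(cfg)
  ps <- net$ps
  # zero the output-projection weights of every MGFL main path
  for (nm in grep("^mgfl\\..*\\.out\\.W$", ps$order, value = TRUE))
    ps$params[[nm]]$value[] <- 0
  set.seed(21)
  N <- 20
  feats <- list(values = matrix(rnorm(N * 15), N, 15),
                centroids = matrix(rnorm(N * 3), N, 3),
                normals = random_unit_normals(N, seed = 22))
  out <- dentalseg:::nf_forward(net, feats, training = FALSE)
  # recompute the expected stage-1 output from the shortcut alone
  g <- dentalseg:::ad_graph()
  aligned <- dentalseg:::ad_const(g, out$aligned$value)
  shortS <- dentalseg:::ad_dense(g, ps, "mgfl.S1.short", aligned,
                                 cfg$mgfl_dims[1], training = FALSE,
                                 relu = FALSE)
  shortL <- dentalseg:::ad_dense(g, ps, "mgfl.L1.short", aligned,
                                 cfg$mgfl_dims[1], training = FALSE,
                                 relu = FALSE)
  # main paths end in batch norm whose beta is still learned zero -> the sum
  # reduces to relu(short) for each branch
  expected <- dentalseg:::cpp_relu(shortS$value) +
    dentalseg:::cpp_relu(shortL$value)
  expect_equal(out$s1$value, expected, tolerance = 1e-10)
})

test_that("ablation switches prune the encodings, branches and ECA", {
  expect_error(network_config(use_pk = FALSE, use_nk = FALSE), "use_pk")
  expect_error(network_config(use_branch_S = FALSE, use_branch_L = FALSE),
               "branch")

  set.seed(23)
  N <- 25
  feats <- list(values = matrix(rnorm(N * 15), N, 15),
                centroids = matrix(rnorm(N * 3), N, 3),
                normals = random_unit_normals(N, seed = 24))

  pk_only <- init_network(tiny_config(use_nk = FALSE))
  expect_equal(nrow(pk_only$ps$params[["mgfl.S1.gie.W"]]$value), 10L)
  both <- init_network(tiny_config())
  expect_equal(nrow(both$ps$params[["mgfl.S1.gie.W"]]$value), 20L)

  solo <- init_network(tiny_config(use_branch_L = FALSE))
  expect_false(any(grepl("^mgfl\\.L", solo$ps$order)))
  out <- dentalseg:::nf_forward(solo, feats, training = FALSE)
  expect_equal(dim(out$probs$value), c(N, 15L))

  no_eca <- init_network(tiny_config(use_eca = FALSE))
  expect_false(any(grepl("^head\\.eca", no_eca$ps$order)))
  out2 <- dentalseg:::nf_forward(no_eca, feats, training = FALSE)
  expect_equal(dim(out2$probs$value), c(N, 15L))
  expect_lt(max(abs(rowSums(out2$probs$value) - 1)), 1e-5)
})

test_that("the forward pass is permutation-equivariant and translation-invariant", {
  arch <- small_arch(150, seed = 13)
  cfg <- tiny_config()
  net <- init_network(cfg)
  feats <- assemble_features(arch, center = TRUE)
  out <- forward_network(net, feats)

  set.seed(26)
  perm <- sample(n_faces(arch))
  pf <- list(values = feats$values[perm, ], centroids = feats$centroids[perm, ],
             normals = feats$normals[perm, ], labels = feats$labels[perm],
             n_classes = feats$n_classes)
  class(pf) <- "face_features"
  outp <- forward_network(net, pf)
  expect_lt(max(abs(outp$probabilities - out$probabilities[perm, ])), 1e-5)

  shifted <- arch
  shifted$vertices <- arch$vertices +
    matrix(c(17, -6, 4), n_vertices(arch), 3, byrow = TRUE)
  outs <- forward_network(net, assemble_features(shifted, center = TRUE))
  expect_lt(max(abs(outs$probabilities - out$probabilities)), 1e-5)
})

test_that("duplicated faces receive the predictions of their originals", {
  arch <- small_arch(100, seed = 27)
  cfg <- tiny_config()
  net <- init_network(cfg)
  feats <- assemble_features(arch, center = TRUE)
  N <- nrow(feats$values)
  set.seed(28)
  perm <- sample(2 * N)
  dup <- list(values = rbind(feats$values, feats$values)[perm, ],
              centroids = rbind(feats$centroids, feats$centroids)[perm, ],
              normals = rbind(feats$normals, feats$normals)[perm, ],
              labels = NULL, n_classes = feats$n_classes)
  class(dup) <- "face_features"
  outd <- forward_network(net, dup)
  orig_of <- rep(seq_len(N), 2)[perm]
  # each duplicate pair agrees with itself
  for (i in seq_len(N)) {
    rows <- which(orig_of == i)
    expect_lt(max(abs(outd$probabilities[rows[1], ] -
                        outd$probabilities[rows[2], ])), 1e-6)
  }
})

test_that("one backward pass reaches every trainable tensor on a 200-face mesh", {
  arch <- small_arch(200, seed = 29)
  cfg <- network_config(mgfl_dims = c(16L, 24L), head_dims = c(20L, 12L),
                        dropout = 0.5, seed = 31L)
  net <- init_network(cfg)
  feats <- assemble_features(arch, center = TRUE)
  out <- dentalseg:::with_seed(1, {
    o <- dentalseg:::nf_forward(net, feats, training = TRUE)
    loss <- dentalseg:::ad_gdl(o$g, o$probs, feats$labels)
    dentalseg:::ad_backward(o$g, loss)
    o
  })
  ps <- net$ps
  for (nm in ps$order) {
    expect_false(is.null(ps$params[[nm]]$grad), label = paste("grad of", nm))
    expect_gt(max(abs(ps$params[[nm]]$grad)), 0, label = paste("nonzero", nm))
  }
})

test_that("analytic gradients match finite differences on a tiny network", {
  cfg <- network_config(K_small = 2L, K_large = 5L, mgfl_dims = c(6L, 8L),
                        head_dims = c(8L, 6L), C = 4L, dropout = 0,
                        seed = 33L)
  net <- init_network(cfg)
  set.seed(34)
  N <- 18
  feats <- list(values = matrix(rnorm(N * 15), N, 15),
                centroids = matrix(rnorm(N * 3), N, 3),
                normals = random_unit_normals(N, seed = 35))
  labels <- sample(0:3, N, replace = TRUE)
  out <- dentalseg:::nf_forward(net, feats, training = TRUE)
  loss <- dentalseg:::ad_gdl(out$g, out$probs, labels)
  dentalseg:::ad_backward(out$g, loss)
  ps <- net$ps
  lossval <- function() {
    o <- dentalseg:::nf_forward(net, feats, training = TRUE)
    generalized_dice_loss(o$probs$value, labels)
  }
  set.seed(36)
  for (trial in 1:12) {
    nm <- sample(ps$order, 1)
    p <- ps$params[[nm]]
    i <- sample(length(p$value), 1)
    h <- 1e-5
    v0 <- p$value[i]
    p$value[i] <- v0 + h; lp <- lossval()
    p$value[i] <- v0 - h; lm <- lossval()
    p$value[i] <- v0
    num <- (lp - lm) / (2 * h)
    expect_lt(abs(num - p$grad[i]),
              1e-4 * max(1, abs(num) + abs(p$grad[i])))
  }
})

test_that("meshes smaller than K_large are rejected with both numbers named", {
  cfg <- tiny_config()
  net <- init_network(cfg)
  tiny <- list(values = matrix(rnorm(4 * 15), 4, 15),
               centroids = matrix(rnorm(12), 4, 3),
               normals = random_unit_normals(4),
               labels = NULL, n_classes = 15L)
  class(tiny) <- "face_features"
  expect_error(forward_network(net, tiny), "4 faces.*K_large = 6")
})
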