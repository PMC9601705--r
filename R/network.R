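#' Network configuration
#'
#' Collects every architectural hyperparameter of the segmentation network:
#' the two K-nearest-neighbour receptive fields, the widths of the two MGFL
#' stages and of the MLP head, the efficient-channel-attention kernel
#' parameters, dropout, and the ablation switches.
#'
#' @param C class count (default 15: gingiva + 14 teeth).
#' @param K_small,K_large neighbourhood sizes of the two MGFL branches
#'   (defaults 3 and 20; `K_small < K_large`).
#' @param mgfl_dims output widths of MGFL stages 1 and 2 (default 128, 512).
#' @param head_dims output widths of MLP-1 and MLP-2 in the fusion head
#'   (default 256, 128); MLP-3 always emits `C`.
#' @param eca_gamma,eca_b fixed parameters of the adaptive ECA kernel-size
#'   rule (defaults 2 and 1).
#' @param dropout dropout rate on the head (default 0.5).
#' @param use_pk,use_nk include the centroid / normal-vector neighbourhood
#'   encodings (at least one must be TRUE).
#' @param use_branch_S,use_branch_L include the small / large receptive-field
#'   MGFL branch (at least one must be TRUE).
#' @param use_eca apply efficient channel attention after MLP-1 and MLP-2.
#' @param include_stage1 also concatenate the stage-1 features into the
#'   local/global fusion (off by default).
#' @param center expect globally centered coordinates (see
#'   [assemble_features()]).
#' @param seed integer seed for weight initialization and dropout.
#' @return A `network_config` list.
#' @export
network_config <- function(C = 15L, K_small = 3L, K_large = 20L,
                           mgfl_dims = c(128L, 512L),
                           head_dims = c(256L, 128L),
                           eca_gamma = 2, eca_b = 1, dropout = 0.5,
                           use_pk = TRUE, use_nk = TRUE,
                           use_branch_S = TRUE, use_branch_L = TRUE,
                           use_eca = TRUE, include_stage1 = FALSE,
                           center = TRUE, seed = 1L) {
  if (!use_pk && !use_nk)
    stop("at least one of use_pk / use_nk must be TRUE")
  if (!use_branch_S && !use_branch_L)
    stop("at least one MGFL branch must be enabled")
  if (K_small >= K_large) stop("K_small must be < K_large")
  if (any(c(mgfl_dims, head_dims) < 2)) stop("layer widths must be >= 2")
  if (C < 2) stop("C must be >= 2")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(list(C = as.integer(C), K_small = as.integer(K_small),
                 K_large = as.integer(K_large),
                 mgfl_dims = as.integer(mgfl_dims),
                 head_dims = as.integer(head_dims),
                 eca_gamma = eca_gamma, eca_b = eca_b, dropout = dropout,
                 use_pk = use_pk, use_nk = use_nk,
                 use_branch_S = use_branch_S, use_branch_L = use_branch_L,
                 use_eca = use_eca, include_stage1 = include_stage1,
                 center = center, seed = as.integer(seed)),
            class = "network_config")
}

#' Neighbourhood geometry encodings
#'
#' For each face *i* and each of its K neighbours *k* (self included),
#' `encode_centroid_geometry()` concatenates the face centroid `p_i`, the
#' neighbour centroid `p_ik`, their difference and the Euclidean distance
#' (10 channels); `encode_normal_geometry()` concatenates the unit normals
#' `nor_i`, `nor_ik`, their difference and their cosine similarity (10
#' channels; the cosine with a zero vector — a degenerate face — is 0).
#'
#' @param centroids,normals numeric N x 3 matrices.
#' @param nbr integer N x K neighbourhood index from [knn_indices()].
#' @return numeric array `N x K x 10`.
#' @export
encode_centroid_geometry <- function(centroids, nbr) {
  flat <- enc_centroid_flat(centroids, nbr)
  flat_to_array(flat, nrow(nbr), ncol(nbr))
}

#' @rdname encode_centroid_geometry
#' @export
encode_normal_geometry <- function(normals, nbr) {
  flat <- enc_normal_flat(normals, nbr)
  flat_to_array(flat, nrow(nbr), ncol(nbr))
}

flat_to_array <- function(flat, N, K) {
  aperm(array(flat, c(K, N, ncol(flat))), c(2L, 1L, 3L))
}

# flattened layouts: row (i-1)*K + k
enc_centroid_flat <- function(centroids, nbr) {
  N <- nrow(nbr); K <- ncol(nbr)
  self_idx <- rep(seq_len(N), each = K)
  nb_idx <- as.vector(t(nbr))
  pi_ <- centroids[self_idx, , drop = FALSE]
  pik <- centroids[nb_idx, , drop = FALSE]
  rel <- pi_ - pik
  cbind(pi_, pik, rel, sqrt(rowSums(rel^2)))
}

enc_normal_flat <- function(normals, nbr) {
  N <- nrow(nbr); K <- ncol(nbr)
  self_idx <- rep(seq_len(N), each = K)
  nb_idx <- as.vector(t(nbr))
  ni <- normals[self_idx, , drop = FALSE]
  nik <- normals[nb_idx, , drop = FALSE]
  # normals are unit (or exactly zero for degenerate faces), so the dot
  # product is the cosine; zero vectors yield cosine 0 by construction
  cbind(ni, nik, ni - nik, rowSums(ni * nik))
}

#' Initialize a segmentation network
#'
#' Creates every weight tensor of the network described by `config`,
#' deterministically from `config$seed` (He initialization for the shared
#' MLPs; the final T-Net layer starts at zero so the transform starts at the
#' identity).
#'
#' @param config a [network_config()].
#' @return A `dental_network` object.
#' @export
init_network <- function(config = network_config()) {
  ps <- param_store()
  net <- structure(list(ps = ps, config = config), class = "dental_network")
  with_seed(config$seed, {
    N0 <- config$K_large
    feats <- list(values = matrix(stats::rnorm(N0 * 15), N0, 15),
                  centroids = matrix(stats::rnorm(N0 * 3), N0, 3),
                  normals = matrix(0, N0, 3))
    feats$normals[, 3] <- 1
    nf_forward(net, feats, training = FALSE)
  })
  net
}

#' @export
print.dental_network <- function(x, ...) {
  np <- sum(vapply(ls(x$ps$params), function(nm)
    length(x$ps$params[[nm]]$value), numeric(1)))
  cat(sprintf(
    "dental_network: C=%d, K=(%d,%d), MGFL dims (%s), head (%s), %s params\n",
    x$config$C, x$config$K_small, x$config$K_large,
    paste(x$config$mgfl_dims, collapse = ", "),
    paste(x$config$head_dims, collapse = ", "),
    format(np, big.mark = ",")))
  invisible(x)
}

# full forward pass; returns the graph and every named intermediate node.
# feats: list(values N x 15, centroids, normals) as from assemble_features()
nf_forward <- function(net, feats, training, nbr_small = NULL,
                       nbr_large = NULL) {
  cfg <- net$config
  ps <- net$ps
  N <- nrow(feats$values)
  if (N < cfg$K_large)
    stop(sprintf("mesh has %d faces but the network needs at least K_large = %d",
                 N, cfg$K_large))
  g <- ad_graph()
  x0 <- ad_const(g, feats$values)
  tn <- ad_tnet(g, ps, x0, training, d = ncol(feats$values))
  aligned <- tn$aligned

  branch_encodings <- function(nbr) {
    parts <- list()
    if (cfg$use_pk) parts <- c(parts, list(enc_centroid_flat(feats$centroids, nbr)))
    if (cfg$use_nk) parts <- c(parts, list(enc_normal_flat(feats$normals, nbr)))
    do.call(cbind, parts)
  }
  if (cfg$use_branch_S) {
    if (is.null(nbr_small)) nbr_small <- knn_indices(feats$centroids, cfg$K_small)
    encS <- branch_encodings(nbr_small)
    idxS <- as.vector(t(nbr_small))
  }
  if (cfg$use_branch_L) {
    if (is.null(nbr_large)) nbr_large <- knn_indices(feats$centroids, cfg$K_large)
    encL <- branch_encodings(nbr_large)
    idxL <- as.vector(t(nbr_large))
  }

  stage <- function(x, stage_id, out_dim) {
    outs <- list()
    if (cfg$use_branch_S)
      outs <- c(outs, list(ad_mgfl(g, ps, sprintf("mgfl.S%d", stage_id), x,
                                   encS, idxS, N, cfg$K_small, out_dim,
                                   training)))
    if (cfg$use_branch_L)
      outs <- c(outs, list(ad_mgfl(g, ps, sprintf("mgfl.L%d", stage_id), x,
                                   encL, idxL, N, cfg$K_large, out_dim,
                                   training)))
    if (length(outs) == 2L) ad_add(g, outs[[1]], outs[[2]]) else outs[[1]]
  }
  s1 <- stage(aligned, 1L, cfg$mgfl_dims[1])
  s2 <- stage(s1, 2L, cfg$mgfl_dims[2])

  global <- ad_maxpool_rows(g, s2)
  tiled <- ad_gather_rows(g, global, rep(1L, N))
  fusion_parts <- list(aligned, s2, tiled)
  if (cfg$include_stage1) fusion_parts <- c(fusion_parts, list(s1))
  fusion <- ad_concat_cols(g, fusion_parts)

  h <- ad_dense(g, ps, "head.mlp1", fusion, cfg$head_dims[1], training)
  if (cfg$use_eca) h <- ad_eca(g, ps, "head.eca1", h, cfg$eca_gamma, cfg$eca_b)
  h <- ad_dense(g, ps, "head.mlp2", h, cfg$head_dims[2], training)
  if (cfg$use_eca) h <- ad_eca(g, ps, "head.eca2", h, cfg$eca_gamma, cfg$eca_b)
  h <- ad_dropout(g, h, cfg$dropout, training)
  logits <- ad_dense(g, ps, "head.mlp3", h, cfg$C, training,
                     bn = FALSE, relu = FALSE)
  probs <- ad_softmax_rows(g, logits)
  list(g = g, probs = probs, logits = logits, aligned = aligned,
       tvec = tn$tvec, transform = tn$transform, s1 = s1, s2 = s2)
}

#' Run the network on a mesh or feature matrix
#'
#' Evaluates the trained (or freshly initialized) network in inference mode
#' and returns per-face class probabilities and hard labels.
#'
#' @param net a `dental_network` from [init_network()] or [train_network()].
#' @param x a labeled or unlabeled [triangle_mesh()], or a `face_features`
#'   object from [assemble_features()].
#' @return A `segmentation_result`: list with `probabilities` (N x C, rows
#'   sum to 1), `labels` (integer, 0-based argmax) and `logits`.
#' @export
forward_network <- function(net, x) {
  feats <- if (inherits(x, "face_features")) x
           else assemble_features(x, center = net$config$center)
  out <- nf_forward(net, feats, training = FALSE)
  probs <- out$probs$value
  structure(list(probabilities = probs,
                 labels = as.integer(max.col(probs, ties.method = "first") - 1L),
                 logits = out$logits$value),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("segmentation_result: %d faces x %d classes; %d classes predicted\n",
              nrow(x$probabilities), ncol(x$probabilities),
              length(unique(x$labels))))
  invisible(x)
}
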