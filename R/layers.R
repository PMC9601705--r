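# Parameter store and the network's building blocks. Parameters are created
# lazily on first use (forward structure is deterministic given the config,
# so creation order -- and therefore seeded initialization -- is too).

param_store <- function() {
  ps <- new.env(parent = emptyenv())
  ps$params <- new.env(parent = emptyenv())
  ps$states <- new.env(parent = emptyenv())
  ps$order <- character()
  ps$step <- 0L
  ps
}

get_param <- function(ps, name, nr, nc,
                      init = c("he", "zero", "one", "small", "tiny")) {
  p <- ps$params[[name]]
  if (!is.null(p)) return(p)
  init <- match.arg(init)
  value <- switch(init,
    he = matrix(stats::rnorm(nr * nc, sd = sqrt(2 / nr)), nr, nc),
    zero = matrix(0, nr, nc),
    one = matrix(1, nr, nc),
    small = matrix(stats::rnorm(nr * nc, sd = 0.1), nr, nc),
    tiny = matrix(stats::rnorm(nr * nc, sd = 1e-5), nr, nc)
  )
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- NULL
  p$m <- matrix(0, nr, nc)
  p$v <- matrix(0, nr, nc)
  ps$params[[name]] <- p
  ps$order <- c(ps$order, name)
  p
}

get_bn_state <- function(ps, name, C) {
  s <- ps$states[[name]]
  if (!is.null(s)) return(s)
  s <- new.env(parent = emptyenv())
  s$mean <- rep(0, C)
  s$var <- rep(1, C)
  ps$states[[name]] <- s
  s
}

# shared (pointwise) MLP layer: linear, then optionally batch norm over the
# rows and a ReLU. With batch norm the linear layer carries no bias (the BN
# shift absorbs it).
ad_dense <- function(g, ps, name, x, out_dim, training,
                     bn = TRUE, relu = TRUE, init = "he") {
  in_dim <- ncol(x$value)
  W <- get_param(ps, paste0(name, ".W"), in_dim, out_dim, init = init)
  y <- ad_mm(g, x, ad_leaf(g, W))
  if (bn) {
    gamma <- get_param(ps, paste0(name, ".bn.gamma"), 1L, out_dim, "one")
    beta <- get_param(ps, paste0(name, ".bn.beta"), 1L, out_dim, "zero")
    st <- get_bn_state(ps, paste0(name, ".bn"), out_dim)
    y <- ad_bn_act(g, y, ad_leaf(g, gamma), ad_leaf(g, beta), st, training,
                   relu = relu)
  } else {
    b <- get_param(ps, paste0(name, ".b"), 1L, out_dim, "zero")
    y <- ad_add_bias(g, y, ad_leaf(g, b))
    if (relu) y <- ad_relu(g, y)
  }
  y
}

#' Adaptive kernel size for efficient channel attention
#'
#' The cross-channel interaction range grows with the channel count:
#' `t = log2(C) / gamma + b / gamma`, taken to the nearest odd integer by
#' truncating and bumping an even result up to the next odd number, with a
#' floor of 1.
#'
#' @param C channel count (>= 1).
#' @param gamma,b fixed mapping parameters (defaults 2 and 1).
#' @return an odd positive integer kernel size.
#' @export
eca_kernel_size <- function(C, gamma = 2, b = 1) {
  if (C < 1) stop("C must be >= 1")
  t <- log2(C) / gamma + b / gamma
  k <- floor(t)
  if (k %% 2 == 0) k <- k + 1
  max(1L, as.integer(k))
}

# efficient channel attention: mean-pool the faces into a 1 x C channel
# descriptor, 1-D convolve across channels with an adaptive odd kernel,
# sigmoid, and rescale each input channel by its weight
ad_eca <- function(g, ps, name, x, gamma = 2, b = 1) {
  C <- ncol(x$value)
  k <- eca_kernel_size(C, gamma, b)
  w <- get_param(ps, paste0(name, ".conv"), 1L, k, "small")
  desc <- ad_meanpool_rows(g, x)
  conv <- ad_conv1d_channels(g, desc, ad_leaf(g, w))
  wts <- ad_sigmoid(g, conv)
  ad_scale_cols(g, x, wts)
}

# T-Net: pointwise convs 64/128/512 with BN+ReLU, global max pool, FC
# 256/128 with ReLU, and a near-zero-initialized FC to d^2 so the learned
# matrix starts at (numerically) the identity while gradient still reaches
# the tower from the first step. The matrix is added to I before the
# multiply. FC layers act on the single 1 x 512 global descriptor, so they
# use plain biases rather than batch norm.
ad_tnet <- function(g, ps, x, training, d = 15L) {
  h <- ad_dense(g, ps, "tnet.conv1", x, 64L, training)
  h <- ad_dense(g, ps, "tnet.conv2", h, 128L, training)
  h <- ad_dense(g, ps, "tnet.conv3", h, 512L, training)
  gl <- ad_maxpool_rows(g, h)
  fc <- ad_dense(g, ps, "tnet.fc1", gl, 256L, training, bn = FALSE)
  fc <- ad_dense(g, ps, "tnet.fc2", fc, 128L, training, bn = FALSE)
  tvec <- ad_dense(g, ps, "tnet.fc3", fc, d * d, training,
                   bn = FALSE, relu = FALSE, init = "tiny")
  aligned <- ad_apply_transform(g, x, tvec, d)
  list(aligned = aligned, tvec = tvec,
       transform = diag(d) + matrix(as.numeric(tvec$value), d, d))
}

# one MGFL block: shared MLP -> geometric information encoding -> attentive
# aggregation, summed with a projected shortcut and passed through ReLU.
# enc_flat is the (N*K) x 10|20 neighbourhood encoding, nbr_flat the
# flattened (i-major) neighbour index vector.
ad_mgfl <- function(g, ps, name, x, enc_flat, nbr_flat, N, K, out_dim,
                    training) {
  half <- out_dim %/% 2L
  pre <- ad_dense(g, ps, paste0(name, ".pre"), x, half, training)
  enc <- ad_const(g, enc_flat)
  rik <- ad_dense(g, ps, paste0(name, ".gie"), enc, half, training)
  fhat <- ad_gather_concat(g, rik, pre, nbr_flat)
  scores <- ad_dense(g, ps, paste0(name, ".att"), fhat, ncol(fhat$value),
                     training, bn = FALSE, relu = FALSE)
  agg <- ad_attend(g, fhat, scores, N, K)
  main <- ad_dense(g, ps, paste0(name, ".out"), agg, out_dim, training,
                   relu = FALSE)
  short <- ad_dense(g, ps, paste0(name, ".short"), x, out_dim, training,
                    relu = FALSE)
  ad_relu(g, ad_add(g, main, short))
}
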