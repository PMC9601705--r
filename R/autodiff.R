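# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Every intermediate tensor is an environment ("node") holding its value, an
# accumulated gradient, and a backward closure that pushes its gradient to
# its parents. Nodes register on a tape in creation order; ad_backward()
# replays the tape in reverse. Values are plain base-R matrices so BLAS does
# the heavy lifting; node bookkeeping is negligible next to the matmuls.

ad_graph <- function() {
  g <- new.env(parent = emptyenv())
  g$tape <- vector("list", 256L)
  g$n <- 0L
  g
}

ad_node <- function(g, value, backward = NULL, param = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- backward
  nd$param <- param
  g$n <- g$n + 1L
  if (g$n > length(g$tape)) length(g$tape) <- 2L * length(g$tape)
  g$tape[[g$n]] <- nd
  nd
}

ad_const <- function(g, value) ad_node(g, value)

# leaf node bound to a parameter environment; after backward the gradient is
# accumulated into param$grad
ad_leaf <- function(g, param) ad_node(g, param$value, param = param)

ad_accum <- function(node, grad) {
  if (is.null(node$grad)) node$grad <- grad
  else node$grad <- node$grad + grad
  invisible(NULL)
}

ad_backward <- function(g, loss, scale = 1) {
  loss$grad <- matrix(scale, 1, 1)
  for (i in seq.int(g$n, 1L)) {
    nd <- g$tape[[i]]
    if (is.null(nd$grad)) next
    if (!is.null(nd$backward)) nd$backward(nd$grad)
    if (!is.null(nd$param)) {
      p <- nd$param
      if (is.null(p$grad)) p$grad <- nd$grad else p$grad <- p$grad + nd$grad
    }
  }
  invisible(NULL)
}

# ---- primitive ops ------------------------------------------------------

ad_mm <- function(g, a, b) {
  av <- a$value; bv <- b$value
  ad_node(g, av %*% bv, backward = function(gr) {
    ad_accum(a, gr %*% t(bv))
    ad_accum(b, crossprod(av, gr))
  })
}

ad_add <- function(g, a, b) {
  ad_node(g, a$value + b$value, backward = function(gr) {
    ad_accum(a, gr)
    ad_accum(b, gr)
  })
}

# fast column-wise recycling helpers (x is N x C, v length C)
col_mul <- function(x, v) x * rep(v, each = nrow(x))
col_add <- function(x, v) x + rep(v, each = nrow(x))

# add a 1 x C bias row to every row of a
ad_add_bias <- function(g, a, b) {
  bv <- as.numeric(b$value)
  ad_node(g, col_add(a$value, bv), backward = function(gr) {
    ad_accum(a, gr)
    ad_accum(b, matrix(colSums(gr), 1L))
  })
}

ad_relu <- function(g, a) {
  y <- cpp_relu(a$value)
  ad_node(g, y, backward = function(gr) ad_accum(a, cpp_relu_backward(gr, y)))
}

ad_sigmoid <- function(g, a) {
  s <- 1 / (1 + exp(-a$value))
  ad_node(g, s, backward = function(gr) ad_accum(a, gr * s * (1 - s)))
}

ad_mul <- function(g, a, b) {
  av <- a$value; bv <- b$value
  ad_node(g, av * bv, backward = function(gr) {
    ad_accum(a, gr * bv)
    ad_accum(b, gr * av)
  })
}

# scale each column of a (N x C) by the matching entry of w (1 x C)
ad_scale_cols <- function(g, a, w) {
  av <- a$value; wv <- as.numeric(w$value)
  ad_node(g, col_mul(av, wv), backward = function(gr) {
    ad_accum(a, col_mul(gr, wv))
    ad_accum(w, matrix(colSums(gr * av), 1L))
  })
}

# rows of a indexed by idx (with repetitions); backward scatter-adds
ad_gather_rows <- function(g, a, idx) {
  nr <- nrow(a$value)
  idx <- as.integer(idx)
  ad_node(g, cpp_gather_rows(a$value, idx), backward = function(gr) {
    ad_accum(a, cpp_scatter_add_rows(gr, idx, nr))
  })
}

# sum rows within contiguous equal-size groups: a is (N*K) x C with row
# (i-1)*K + k; result is N x C
ad_group_rowsum <- function(g, a, n_groups, K) {
  ad_node(g, cpp_group_rowsum(a$value, K), backward = function(gr) {
    ad_accum(a, cpp_group_expand(gr, K))
  })
}

# fused attention aggregation: per-channel softmax of the scores over each
# group of K neighbours, then the weighted sum of the feature slots
ad_attend <- function(g, fhat, scores, n_groups, K) {
  fv <- fhat$value
  fw <- cpp_attend_forward(fv, scores$value, K)
  soft <- fw$soft
  ad_node(g, fw$agg, backward = function(gr) {
    bw <- cpp_attend_backward(gr, fv, soft, K)
    ad_accum(fhat, bw$dfhat)
    ad_accum(scores, bw$dscores)
  })
}

# fused neighbour gather + concat: value is [ a , b[idx, ] ]
ad_gather_concat <- function(g, a, b, idx) {
  idx <- as.integer(idx)
  ca <- ncol(a$value)
  nb <- nrow(b$value)
  ad_node(g, cpp_gather_concat(a$value, b$value, idx),
          backward = function(gr) {
    ad_accum(a, gr[, seq_len(ca), drop = FALSE])
    ad_accum(b, cpp_scatter_add_rows(gr[, -seq_len(ca), drop = FALSE],
                                     idx, nb))
  })
}

# column-wise softmax over the K rows of each contiguous group
ad_group_softmax <- function(g, a, n_groups, K) {
  soft <- cpp_group_softmax(a$value, K)
  ad_node(g, soft, backward = function(gr) {
    ad_accum(a, cpp_group_softmax_backward(gr, soft, K))
  })
}

# row-wise softmax (N x C)
ad_softmax_rows <- function(g, a) {
  av <- a$value
  mx <- av[cbind(seq_len(nrow(av)), max.col(av, ties.method = "first"))]
  e <- exp(av - mx)
  s <- e / rowSums(e)
  ad_node(g, s, backward = function(gr) {
    ad_accum(a, s * (gr - rowSums(gr * s)))
  })
}

# column maxima -> 1 x C (global max pool over faces)
ad_maxpool_rows <- function(g, a) {
  av <- a$value
  amax <- max.col(t(av), ties.method = "first")
  val <- matrix(av[cbind(amax, seq_len(ncol(av)))], 1L)
  ad_node(g, val, backward = function(gr) {
    z <- matrix(0, nrow(av), ncol(av))
    z[cbind(amax, seq_len(ncol(av)))] <- as.numeric(gr)
    ad_accum(a, z)
  })
}

# column means -> 1 x C
ad_meanpool_rows <- function(g, a) {
  n <- nrow(a$value)
  ad_node(g, matrix(colMeans(a$value), 1L), backward = function(gr) {
    ad_accum(a, matrix(rep(as.numeric(gr) / n, each = n), n))
  })
}

ad_concat_cols <- function(g, nodes) {
  vals <- lapply(nodes, function(nd) nd$value)
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_node(g, do.call(cbind, vals), backward = function(gr) {
    for (j in seq_along(nodes))
      ad_accum(nodes[[j]], gr[, starts[j]:ends[j], drop = FALSE])
  })
}

ad_dropout <- function(g, a, p, training) {
  if (!training || p <= 0) return(a)
  mask <- (matrix(stats::runif(length(a$value)), nrow(a$value)) >= p) / (1 - p)
  ad_node(g, a$value * mask, backward = function(gr) ad_accum(a, gr * mask))
}

# fused batch norm + optional ReLU (the workhorse of every shared MLP):
# value, normalized input and all three gradients are computed in single
# C++ passes to limit allocation churn on the (N*K)-row tensors
ad_bn_act <- function(g, a, gamma, beta, state, training, relu = TRUE,
                      momentum = 0.1, eps = 1e-5) {
  av <- a$value
  n <- nrow(av)
  gv <- as.numeric(gamma$value)
  bv <- as.numeric(beta$value)
  if (training && n > 1L) {
    mv <- cpp_col_mean_var(av)
    mu <- mv$mean
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * mv$var * n / (n - 1)
    inv <- 1 / sqrt(mv$var + eps)
    batch_stats <- TRUE
  } else {
    mu <- state$mean
    inv <- 1 / sqrt(state$var + eps)
    batch_stats <- FALSE
  }
  fw <- cpp_bn_act_forward(av, mu, inv, gv, bv, relu)
  y <- fw$y
  xhat <- fw$xhat
  ad_node(g, y, backward = function(gr) {
    bw <- cpp_bn_act_backward(gr, y, xhat, gv, inv, batch_stats, relu)
    ad_accum(a, bw$dx)
    ad_accum(gamma, matrix(bw$dgamma, 1L))
    ad_accum(beta, matrix(bw$dbeta, 1L))
  })
}

# zero-padded 1-D convolution across the channel axis of a 1 x C descriptor
# with a length-k kernel (k odd)
ad_conv1d_channels <- function(g, a, w) {
  av <- as.numeric(a$value)
  wv <- as.numeric(w$value)
  k <- length(wv)
  C <- length(av)
  half <- (k - 1L) %/% 2L
  pad <- c(rep(0, half), av, rep(0, half))
  val <- numeric(C)
  for (j in seq_len(k)) val <- val + wv[j] * pad[seq_len(C) + j - 1L]
  ad_node(g, matrix(val, 1L), backward = function(gr) {
    grv <- as.numeric(gr)
    gw <- numeric(k)
    for (j in seq_len(k)) gw[j] <- sum(grv * pad[seq_len(C) + j - 1L])
    gpad <- numeric(C + 2L * half)
    for (j in seq_len(k))
      gpad[seq_len(C) + j - 1L] <- gpad[seq_len(C) + j - 1L] + wv[j] * grv
    ad_accum(a, matrix(gpad[half + seq_len(C)], 1L))
    ad_accum(w, matrix(gw, nrow(w$value), ncol(w$value)))
  })
}

# aligned = F %*% (I + matrix(tvec, d, d)); tvec is a 1 x d^2 row vector
# reshaped column-major
ad_apply_transform <- function(g, f, tvec, d) {
  Tm <- diag(d) + matrix(as.numeric(tvec$value), d, d)
  fv <- f$value
  ad_node(g, fv %*% Tm, backward = function(gr) {
    ad_accum(f, gr %*% t(Tm))
    ad_accum(tvec, matrix(as.numeric(crossprod(fv, gr)), 1L))
  })
}

# generalized Dice loss as a scalar node; probs is N x C, labels in 0..C-1.
# weights w_l = 1 / (sum_n r_nl + eps)^2; classes absent from the batch
# contribute through eps only.
ad_gdl <- function(g, probs, labels, eps = 1e-6) {
  pv <- probs$value
  N <- nrow(pv); C <- ncol(pv)
  r <- matrix(0, N, C)
  r[cbind(seq_len(N), labels + 1L)] <- 1
  w <- 1 / (colSums(r) + eps)^2
  num <- sum(w * colSums(r * pv))
  den <- sum(w * colSums(r + pv)) + eps
  val <- 1 - 2 * num / den
  ad_node(g, matrix(val, 1L, 1L), backward = function(gr) {
    gs <- as.numeric(gr)
    # d/dp_nl: -2 * (w_l r_nl den - num w_l) / den^2
    grad <- -2 * (sweep(r, 2L, w, "*") * den -
                    matrix(num * w, N, C, byrow = TRUE)) / den^2
    ad_accum(probs, gs * grad)
  })
}
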