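# Differentiable array operations built on the autodiff engine.
# All 4-axis feature maps follow the (batch, channel, height, width) layout.

# ---- shape helpers ---------------------------------------------------------

# (N,C,H,W) -> matrix with N*H*W rows and C columns (channel-wise view)
chan_mat <- function(x) matrix(aperm(x, c(1, 3, 4, 2)), ncol = dim(x)[2])

# inverse of chan_mat for a target dim d = c(N,C,H,W)
unchan_mat <- function(m, d) aperm(array(m, c(d[1], d[3], d[4], d[2])), c(1, 4, 2, 3))

# sum `a` down to a target dim that may have 1s where `a` is larger
sum_axis <- function(a, ax) {
  d <- dim(a)
  nd <- length(d)
  perm <- c(setdiff(seq_len(nd), ax), ax)
  s <- array(rowSums(matrix(aperm(a, perm), ncol = d[ax])), dim = c(d[perm][-nd], 1L))
  aperm(s, order(perm))
}

sum_to_dim <- function(a, td) {
  for (ax in seq_along(td)) {
    if (td[ax] == 1L && dim(a)[ax] > 1L) a <- sum_axis(a, ax)
  }
  a
}

# broadcast `g` (with 1s on some axes) up to target dim
expand_to_dim <- function(g, td) {
  d <- dim(g)
  if (all(d == td)) return(g)
  idx <- lapply(seq_along(td), function(ax) {
    if (d[ax] == td[ax]) seq_len(d[ax]) else rep(1L, td[ax])
  })
  do.call(`[`, c(list(g), idx, list(drop = FALSE)))
}

node_needs_grad <- function(x) isTRUE(x$requires_grad) || !is.null(x$bw)

# ---- convolution -----------------------------------------------------------

op_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L, dil = 1L) {
  xv <- x$v
  wv <- w$v
  d_in <- dim(xv)
  kh <- dim(wv)[3]
  kw <- dim(wv)[4]
  bv <- if (is.null(b)) NULL else as.numeric(b$v)
  y <- .cpp_conv2d_fwd(xv, wv, bv, as.integer(stride), as.integer(pad), as.integer(dil))
  parents <- c(list(x, w), if (!is.null(b)) list(b))
  ag_node(y, parents, function(g) {
    if (node_needs_grad(x)) {
      ag_accum(x, .cpp_conv2d_bwd_x(g, wv, as.integer(stride), as.integer(pad),
                                    as.integer(dil), d_in[3], d_in[4]))
    }
    ag_accum(w, .cpp_conv2d_bwd_w(xv, g, as.integer(stride), as.integer(pad),
                                  as.integer(dil), kh, kw))
    if (!is.null(b)) ag_accum(b, channel_sums(g))
  })
}

# Transposed convolution with kernel = stride and no padding (exact x`stride`
# upsampling). Weight layout is (C_in, C_out, k, k): the forward pass is the
# input-gradient of a strided convolution, so the roles of the two kernel
# passes swap relative to op_conv2d.
op_convt2d <- function(x, w, b = NULL, stride = 2L) {
  xv <- x$v
  wv <- w$v
  d_in <- dim(xv)
  k <- dim(wv)[3]
  stopifnot(k == stride)
  y <- .cpp_conv2d_bwd_x(xv, wv, as.integer(stride), 0L, 1L,
                         d_in[3] * stride, d_in[4] * stride)
  if (!is.null(b)) y <- y + rep_c(b$v, dim(y)[1])
  parents <- c(list(x, w), if (!is.null(b)) list(b))
  ag_node(y, parents, function(g) {
    if (node_needs_grad(x)) {
      ag_accum(x, .cpp_conv2d_fwd(g, wv, NULL, as.integer(stride), 0L, 1L))
    }
    ag_accum(w, .cpp_conv2d_bwd_w(g, xv, as.integer(stride), 0L, 1L, k, k))
    if (!is.null(b)) ag_accum(b, channel_sums(g))
  })
}

# ---- batch normalisation ---------------------------------------------------

# per-channel sums over (N,H,W); no transposition of the (N,C,H,W) block
channel_sums <- function(x) colSums(rowSums(x, dims = 2L))

# a length N*C vector recycles elementwise over an (N,C,H,W) array, so a
# per-channel vector v broadcasts as rep(v, each = N) without allocating a
# full-size companion array
rep_c <- function(v, N) rep(v, each = N)

# `state` is an environment with running mean `rm` and variance `rv`.
op_bn <- function(x, gamma, beta, state, training = TRUE,
                  momentum = 0.1, eps = 1e-5) {
  xv <- x$v
  d <- dim(xv)
  N <- d[1]
  M <- d[1] * d[3] * d[4]
  if (training) {
    mu <- channel_sums(xv) / M
    xc <- xv - rep_c(mu, N)
    va <- channel_sums(xc * xc) / M
    state$rm <- (1 - momentum) * state$rm + momentum * mu
    state$rv <- (1 - momentum) * state$rv + momentum * va
  } else {
    mu <- state$rm
    va <- state$rv
    xc <- xv - rep_c(mu, N)
  }
  ivstd <- 1 / sqrt(va + eps)
  xhat <- xc * rep_c(ivstd, N)
  y <- xhat * rep_c(gamma$v, N) + rep_c(beta$v, N)
  ag_node(y, list(x, gamma, beta), function(g) {
    ag_accum(gamma, channel_sums(g * xhat))
    ag_accum(beta, channel_sums(g))
    if (node_needs_grad(x)) {
      dxhat <- g * rep_c(gamma$v, N)
      if (training) {
        t1 <- dxhat - rep_c(channel_sums(dxhat) / M, N)
        t2 <- xhat * rep_c(channel_sums(dxhat * xhat) / M, N)
        dx <- (t1 - t2) * rep_c(ivstd, N)
      } else {
        dx <- dxhat * rep_c(ivstd, N)
      }
      ag_accum(x, dx)
    }
  })
}

# ---- pointwise -------------------------------------------------------------

op_relu <- function(x) {
  xv <- x$v
  mask <- xv > 0
  y <- xv
  y[!mask] <- 0
  ag_node(y, list(x), function(g) {
    if (node_needs_grad(x)) ag_accum(x, g * mask)
  })
}

op_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$v))
  ag_node(s, list(x), function(g) {
    if (node_needs_grad(x)) ag_accum(x, g * s * (1 - s))
  })
}

op_add <- function(a, b) {
  ag_node(a$v + b$v, list(a, b), function(g) {
    if (node_needs_grad(a)) ag_accum(a, g)
    if (node_needs_grad(b)) ag_accum(b, g)
  })
}

# y = x * gate, gate broadcast over axes where its dim is 1
op_scale <- function(x, gate) {
  xv <- x$v
  gv <- gate$v
  td <- dim(xv)
  ge <- expand_to_dim(gv, td)
  ag_node(xv * ge, list(x, gate), function(g) {
    if (node_needs_grad(x)) ag_accum(x, g * ge)
    ag_accum(gate, sum_to_dim(g * xv, dim(gv)))
  })
}

op_reshape <- function(x, newdim) {
  olddim <- dim(x$v)
  v <- x$v
  dim(v) <- newdim
  ag_node(v, list(x), function(g) {
    dim(g) <- olddim
    if (node_needs_grad(x)) ag_accum(x, g)
  })
}

# ---- pooling and fully connected -------------------------------------------

# global average pool: (N,C,H,W) -> (N,C) matrix
op_gap <- function(x) {
  d <- dim(x$v)
  z <- rowSums(x$v, dims = 2L) / (d[3] * d[4])
  ag_node(z, list(x), function(g) {
    if (node_needs_grad(x)) ag_accum(x, array(as.vector(g) / (d[3] * d[4]), dim = d))
  })
}

op_linear <- function(x, W, b = NULL) {
  xv <- x$v
  y <- xv %*% W$v
  if (!is.null(b)) y <- sweep(y, 2, b$v, `+`)
  parents <- c(list(x, W), if (!is.null(b)) list(b))
  ag_node(y, parents, function(g) {
    if (node_needs_grad(x)) ag_accum(x, g %*% t(W$v))
    ag_accum(W, crossprod(xv, g))
    if (!is.null(b)) ag_accum(b, colSums(g))
  })
}

# width-wise mean (over W): (N,C,H,W) -> (N,C,H,1)
op_pool_w <- function(x) {
  d <- dim(x$v)
  z <- rowSums(x$v, dims = 3L) / d[4]
  dim(z) <- c(d[1], d[2], d[3], 1L)
  ag_node(z, list(x), function(g) {
    if (node_needs_grad(x)) ag_accum(x, array(as.vector(g) / d[4], dim = d))
  })
}

# height-wise mean (over H): (N,C,H,W) -> (N,C,W,1), positions index width
op_pool_h <- function(x) {
  d <- dim(x$v)
  xp <- aperm(x$v, c(1, 2, 4, 3))
  z <- array(rowMeans(matrix(xp, nrow = d[1] * d[2] * d[4])), c(d[1], d[2], d[4], 1L))
  ag_node(z, list(x), function(g) {
    if (node_needs_grad(x)) {
      gp <- array(as.vector(g) / d[3], dim = c(d[1], d[2], d[4], d[3]))
      ag_accum(x, aperm(gp, c(1, 2, 4, 3)))
    }
  })
}

# concatenate two (N,C,P,1) position maps along the position axis
op_cat_pos <- function(a, b) {
  da <- dim(a$v)
  db <- dim(b$v)
  y <- array(0, c(da[1], da[2], da[3] + db[3], 1L))
  y[, , seq_len(da[3]), ] <- a$v
  y[, , da[3] + seq_len(db[3]), ] <- b$v
  ag_node(y, list(a, b), function(g) {
    if (node_needs_grad(a)) ag_accum(a, g[, , seq_len(da[3]), , drop = FALSE])
    if (node_needs_grad(b)) ag_accum(b, g[, , da[3] + seq_len(db[3]), , drop = FALSE])
  })
}

op_slice_pos <- function(x, from, to) {
  d <- dim(x$v)
  y <- x$v[, , from:to, , drop = FALSE]
  ag_node(y, list(x), function(g) {
    if (node_needs_grad(x)) {
      gx <- array(0, d)
      gx[, , from:to, ] <- g
      ag_accum(x, gx)
    }
  })
}

# swap the height and width axes
op_transpose_hw <- function(x) {
  ag_node(aperm(x$v, c(1, 2, 4, 3)), list(x), function(g) {
    if (node_needs_grad(x)) ag_accum(x, aperm(g, c(1, 2, 4, 3)))
  })
}

# concatenate feature maps along the channel axis
op_cat_c <- function(xs) {
  dims <- lapply(xs, function(x) dim(x$v))
  cs <- vapply(dims, `[`, numeric(1), 2)
  d1 <- dims[[1]]
  y <- array(0, c(d1[1], sum(cs), d1[3], d1[4]))
  off <- 0L
  for (x in xs) {
    cc <- dim(x$v)[2]
    y[, off + seq_len(cc), , ] <- x$v
    off <- off + cc
  }
  ag_node(y, xs, function(g) {
    off <- 0L
    for (x in xs) {
      cc <- dim(x$v)[2]
      if (node_needs_grad(x)) ag_accum(x, g[, off + seq_len(cc), , , drop = FALSE])
      off <- off + cc
    }
  })
}
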