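# Independent loop-based reference implementations used as oracles for the
# vectorised / compiled forward passes. Deliberately naive and slow.

naive_conv2d <- function(x, w, b = NULL, stride = 1, pad = 0, dil = 1) {
  d <- dim(x)
  wd <- dim(w)
  N <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  Co <- wd[1]; kh <- wd[3]; kw <- wd[4]
  Ho <- (H + 2 * pad - dil * (kh - 1) - 1) %/% stride + 1
  Wo <- (W + 2 * pad - dil * (kw - 1) - 1) %/% stride + 1
  y <- array(0, c(N, Co, Ho, Wo))
  for (n in 1:N) for (co in 1:Co) for (ho in 1:Ho) for (wo in 1:Wo) {
    acc <- if (is.null(b)) 0 else b[co]
    for (ci in 1:C) for (i in 1:kh) for (j in 1:kw) {
      h <- (ho - 1) * stride - pad + (i - 1) * dil + 1
      ww <- (wo - 1) * stride - pad + (j - 1) * dil + 1
      if (h >= 1 && h <= H && ww >= 1 && ww <= W) {
        acc <- acc + x[n, ci, h, ww] * w[co, ci, i, j]
      }
    }
    y[n, co, ho, wo] <- acc
  }
  y
}

# inference-mode batch norm with the given running stats
naive_bn_eval <- function(x, gamma, beta, rm, rv, eps = 1e-5) {
  d <- dim(x)
  y <- x
  for (n in 1:d[1]) for (cc in 1:d[2]) {
    y[n, cc, , ] <- gamma[cc] * (x[n, cc, , ] - rm[cc]) / sqrt(rv[cc] + eps) + beta[cc]
  }
  y
}

naive_relu <- function(x) pmax(x, 0)
naive_sigmoid <- function(x) 1 / (1 + exp(-x))

# conv + eval-mode BN + ReLU with fresh (identity) running stats, matching
# the standalone block forwards
naive_cbr <- function(x, cv, bn, stride = 1, pad = 1, dil = 1) {
  C <- dim(cv$w$v)[1]
  naive_relu(naive_bn_eval(naive_conv2d(x, cv$w$v, if (is.null(cv$b)) NULL else cv$b$v,
                                        stride, pad, dil),
                           bn$gamma$v, bn$beta$v, bn$state$rm, bn$state$rv))
}

naive_resblock <- function(x, blk) {
  h <- naive_cbr(x, blk$conv1, blk$bn1)
  h <- naive_cbr(h, blk$conv2, blk$bn2)
  sc <- if (is.null(blk$proj)) x else naive_conv2d(x, blk$proj$w$v, NULL, 1, 0, 1)
  sc + h
}

naive_resstage <- function(x, st) naive_resblock(naive_resblock(x, st$b1), st$b2)

naive_cse <- function(x, p) {
  d <- dim(x)
  y <- x
  for (n in 1:d[1]) {
    z <- vapply(1:d[2], function(cc) mean(x[n, cc, , ]), numeric(1))
    h <- naive_relu(as.vector(z %*% p$fc1$W$v) + p$fc1$b$v)
    s <- naive_sigmoid(as.vector(h %*% p$fc2$W$v) + p$fc2$b$v)
    for (cc in 1:d[2]) y[n, cc, , ] <- s[cc] * x[n, cc, , ]
  }
  y
}

# dense 1x1 convolution applied at each position of a (C, P) profile
naive_pos_conv <- function(z, w, b) {
  # z: C x P; w: (Co, C, 1, 1); returns Co x P
  Co <- dim(w)[1]
  out <- matrix(0, Co, ncol(z))
  for (p in seq_len(ncol(z))) {
    out[, p] <- as.vector(w[, , 1, 1] %*% z[, p, drop = FALSE]) + b
  }
  out
}

naive_ca <- function(x, p) {
  d <- dim(x)
  N <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  y <- x
  for (n in 1:N) {
    zh <- sapply(1:H, function(h) vapply(1:C, function(cc) mean(x[n, cc, h, ]), numeric(1)))  # C x H
    zw <- sapply(1:W, function(w0) vapply(1:C, function(cc) mean(x[n, cc, , w0]), numeric(1))) # C x W
    z <- cbind(zh, zw)                                        # C x (H+W)
    hmid <- naive_relu(naive_pos_conv(z, p$conv1$w$v, p$conv1$b$v))
    ah <- naive_sigmoid(naive_pos_conv(hmid[, 1:H, drop = FALSE], p$convh$w$v, p$convh$b$v))
    aw <- naive_sigmoid(naive_pos_conv(hmid[, (H + 1):(H + W), drop = FALSE],
                                       p$convw$w$v, p$convw$b$v))
    for (cc in 1:C) for (h in 1:H) for (w0 in 1:W) {
      y[n, cc, h, w0] <- x[n, cc, h, w0] * ah[cc, h] * aw[cc, w0]
    }
  }
  y
}

naive_denseaspp <- function(x0, p) {
  sets <- denseaspp_input_sets(p$dilations)$input_sets
  outs <- list()
  for (l in seq_along(p$dilations)) {
    inp <- x0
    for (i in sets[[l]]) inp <- abind_c(inp, outs[[i]])
    dl <- p$dilations[l]
    outs[[l]] <- naive_cbr(inp, p$layers[[l]]$conv, p$layers[[l]]$bn,
                           stride = 1, pad = dl, dil = dl)
  }
  cat_all <- x0
  for (o in outs) cat_all <- abind_c(cat_all, o)
  naive_cbr(cat_all, p$proj, p$proj_bn, stride = 1, pad = 0, dil = 1)
}

abind_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- array(0, c(da[1], da[2] + db[2], da[3], da[4]))
  y[, seq_len(da[2]), , ] <- a
  y[, da[2] + seq_len(db[2]), , ] <- b
  y
}

# per-pixel focal and dice computed with explicit loops
naive_softmax_px <- function(z) { e <- exp(z - max(z)); e / sum(e) }

naive_focal <- function(logits, target, gamma) {
  d <- dim(logits)
  tot <- 0
  for (n in 1:d[1]) for (h in 1:d[3]) for (w in 1:d[4]) {
    pr <- naive_softmax_px(logits[n, , h, w])
    pt <- pr[target[n, h, w] + 1]
    tot <- tot + (1 - pt)^gamma * (-log(pt))
  }
  tot / (d[1] * d[3] * d[4])
}

naive_dice_per_class <- function(probs, oh, eps) {
  d <- dim(probs)
  vapply(1:d[2], function(cc) {
    num <- 0; dp <- 0; dt <- 0
    for (n in 1:d[1]) for (h in 1:d[3]) for (w in 1:d[4]) {
      num <- num + probs[n, cc, h, w] * oh[n, cc, h, w]
      dp <- dp + probs[n, cc, h, w]
      dt <- dt + oh[n, cc, h, w]
    }
    (2 * num + eps) / (dp + dt + eps)
  }, numeric(1))
}

# exhaustive directed Hausdorff on point matrices (rows = points, mm units)
naive_directed_h <- function(P, Q) {
  worst <- 0
  for (i in seq_len(nrow(P))) {
    best <- Inf
    for (j in seq_len(nrow(Q))) {
      best <- min(best, sqrt(sum((P[i, ] - Q[j, ])^2)))
    }
    worst <- max(worst, best)
  }
  worst
}

naive_min_dists <- function(P, Q) {
  vapply(seq_len(nrow(P)), function(i) {
    min(vapply(seq_len(nrow(Q)), function(j) sqrt(sum((P[i, ] - Q[j, ])^2)), numeric(1)))
  }, numeric(1))
}

# random small feature map
rand_fm <- function(N, C, H, W) array(rnorm(N * C * H * W), c(N, C, H, W))

# small random blob mask for metric tests
rand_mask <- function(d, p = 0.1) array(runif(prod(d)) < p, d)
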