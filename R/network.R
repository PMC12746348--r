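# SCDU-Net: cascaded residual encoder with spatial-channel dual attention,
# selectively connected dense atrous spatial pyramid pooling bottleneck,
# and a symmetric transposed-convolution decoder.

#' Network configuration
#'
#' Describes the SCDU-Net topology. Channels double at every downsampling,
#' so with `stages = 4` and `base_channels = 64` the bottleneck carries
#' 1024 channels; the test preset uses `base_channels = 8` (bottleneck 128).
#'
#' @param in_channels Number of input image channels (1 for T2-weighted MRI).
#' @param num_classes Number of output classes (3: background, GTVp, GTVn).
#' @param base_channels Channel width of the first encoder stage.
#' @param stages Number of downsampling (and upsampling) stages.
#' @param reduction Channel reduction ratio `r` shared by the
#'   squeeze-and-excitation and coordinate attention branches; the reduced
#'   width is floored at 4.
#' @param aspp_dilations Strictly increasing dilation rates of the dense
#'   atrous pyramid branches.
#' @param aspp_growth Channels produced by each pyramid branch; default is
#'   a quarter of the bottleneck width.
#' @param sc_placement Where the spatial-channel attention block sits:
#'   after each encoder residual stage (`"encoder"`, the default), after
#'   each decoder stage (`"decoder"`), or `"both"`.
#' @param upsample Decoder upsampling operator: `"transposed"` (2x2
#'   transposed convolution, default) or `"bilinear"` (fixed bilinear
#'   upsampling followed by a 3x3 convolution).
#' @param seed Seed for weight initialisation (Kaiming-uniform).
#' @return A `scdunet_config` list.
#' @export
network_config <- function(in_channels = 1L, num_classes = 3L,
                           base_channels = 64L, stages = 4L,
                           reduction = 16L, aspp_dilations = c(1L, 2L, 3L),
                           aspp_growth = NULL,
                           sc_placement = c("encoder", "decoder", "both"),
                           upsample = c("transposed", "bilinear"),
                           seed = 1L) {
  sc_placement <- match.arg(sc_placement)
  upsample <- match.arg(upsample)
  if (stages < 1L) stop("`stages` must be >= 1")
  if (base_channels < 1L || in_channels < 1L || num_classes < 2L) {
    stop("channel and class counts must be positive (num_classes >= 2)")
  }
  aspp_dilations <- as.integer(aspp_dilations)
  if (length(aspp_dilations) < 1L || any(aspp_dilations < 1L) ||
      any(diff(aspp_dilations) <= 0L)) {
    stop("`aspp_dilations` must be a strictly increasing list of positive integers")
  }
  bottleneck <- base_channels * 2L^stages
  if (is.null(aspp_growth)) aspp_growth <- max(4L, bottleneck %/% 4L)
  structure(list(
    in_channels = as.integer(in_channels),
    num_classes = as.integer(num_classes),
    base_channels = as.integer(base_channels),
    stages = as.integer(stages),
    reduction = as.integer(reduction),
    aspp_dilations = aspp_dilations,
    aspp_growth = as.integer(aspp_growth),
    sc_placement = sc_placement,
    upsample = upsample,
    seed = as.integer(seed)
  ), class = "scdunet_config")
}

reduced_width <- function(C, r) max(4L, C %/% r)

# ---- parameter constructors (Kaiming-uniform init) -------------------------

new_conv <- function(Ci, Co, k, stride = 1L, pad = (k - 1L) %/% 2L,
                     dil = 1L, bias = FALSE) {
  bound <- sqrt(6 / (Ci * k * k))
  w <- array(runif(Co * Ci * k * k, -bound, bound), c(Co, Ci, k, k))
  list(w = ag_leaf(w, requires_grad = TRUE),
       b = if (bias) ag_leaf(numeric(Co), requires_grad = TRUE) else NULL,
       stride = as.integer(stride), pad = as.integer(pad), dil = as.integer(dil))
}

# "same"-padded dilated 3x3 convolution for the pyramid branches
new_dil_conv <- function(Ci, Co, k, dil) {
  new_conv(Ci, Co, k, stride = 1L, pad = dil * ((k - 1L) %/% 2L), dil = dil)
}

new_convt <- function(Ci, Co, k = 2L, bias = TRUE) {
  bound <- sqrt(6 / (Ci * k * k))
  w <- array(runif(Ci * Co * k * k, -bound, bound), c(Ci, Co, k, k))
  list(w = ag_leaf(w, requires_grad = TRUE),
       b = if (bias) ag_leaf(numeric(Co), requires_grad = TRUE) else NULL,
       stride = as.integer(k))
}

new_bn <- function(C) {
  state <- new.env(parent = emptyenv())
  state$rm <- numeric(C)
  state$rv <- rep(1, C)
  list(gamma = ag_leaf(rep(1, C), requires_grad = TRUE),
       beta = ag_leaf(numeric(C), requires_grad = TRUE),
       state = state)
}

new_linear <- function(Ci, Co, bias = TRUE) {
  bound <- sqrt(6 / Ci)
  list(W = ag_leaf(matrix(runif(Ci * Co, -bound, bound), Ci, Co), requires_grad = TRUE),
       b = if (bias) ag_leaf(numeric(Co), requires_grad = TRUE) else NULL)
}

new_resblock <- function(Ci, Co) {
  list(conv1 = new_conv(Ci, Co, 3L), bn1 = new_bn(Co),
       conv2 = new_conv(Co, Co, 3L), bn2 = new_bn(Co),
       proj = if (Ci != Co) new_conv(Ci, Co, 1L) else NULL)
}

new_resstage <- function(Ci, Co) list(b1 = new_resblock(Ci, Co), b2 = new_resblock(Co, Co))

new_cse <- function(C, r) {
  h <- reduced_width(C, r)
  list(fc1 = new_linear(C, h), fc2 = new_linear(h, C))
}

new_ca <- function(C, r) {
  h <- reduced_width(C, r)
  list(conv1 = new_conv(C, h, 1L, bias = TRUE),
       convh = new_conv(h, C, 1L, bias = TRUE),
       convw = new_conv(h, C, 1L, bias = TRUE))
}

new_sc <- function(C, r) list(cse = new_cse(C, r), ca = new_ca(C, r))

new_denseaspp <- function(C0, G, dilations) {
  sets <- denseaspp_input_sets(dilations)$input_sets
  layers <- lapply(seq_along(dilations), function(l) {
    Ci <- C0 + G * length(sets[[l]])
    list(conv = new_dil_conv(Ci, G, 3L, dilations[l]), bn = new_bn(G))
  })
  list(dilations = as.integer(dilations), layers = layers,
       proj = new_conv(C0 + G * length(dilations), C0, 1L),
       proj_bn = new_bn(C0))
}

# ---- forward passes --------------------------------------------------------

fw_conv <- function(x, cv) op_conv2d(x, cv$w, cv$b, cv$stride, cv$pad, cv$dil)

fw_bn <- function(x, bn, training) op_bn(x, bn$gamma, bn$beta, bn$state, training)

fw_cbr <- function(x, cv, bn, training) op_relu(fw_bn(fw_conv(x, cv), bn, training))

fw_resblock <- function(x, blk, training) {
  h <- fw_cbr(x, blk$conv1, blk$bn1, training)
  h <- fw_cbr(h, blk$conv2, blk$bn2, training)
  sc <- if (is.null(blk$proj)) x else fw_conv(x, blk$proj)
  op_add(sc, h)
}

fw_resstage <- function(x, st, training) {
  fw_resblock(fw_resblock(x, st$b1, training), st$b2, training)
}

fw_cse <- function(x, p) {
  z <- op_gap(x)
  h <- op_relu(op_linear(z, p$fc1$W, p$fc1$b))
  s <- op_sigmoid(op_linear(h, p$fc2$W, p$fc2$b))
  d <- dim(x$v)
  op_scale(x, op_reshape(s, c(d[1], d[2], 1L, 1L)))
}

fw_ca <- function(x, p) {
  d <- dim(x$v)
  H <- d[3]
  W <- d[4]
  zh <- op_pool_w(x)                       # (N,C,H,1)
  zw <- op_pool_h(x)                       # (N,C,W,1)
  z <- op_cat_pos(zh, zw)                  # (N,C,H+W,1)
  h <- op_relu(fw_conv(z, p$conv1))        # shared C/r projection
  ah <- op_sigmoid(fw_conv(op_slice_pos(h, 1L, H), p$convh))
  aw <- op_sigmoid(fw_conv(op_slice_pos(h, H + 1L, H + W), p$convw))
  op_scale(op_scale(x, ah), op_transpose_hw(aw))
}

fw_sc <- function(x, p) op_add(fw_cse(x, p$cse), fw_ca(x, p$ca))

fw_denseaspp <- function(x0, p, training) {
  sets <- denseaspp_input_sets(p$dilations)$input_sets
  outs <- vector("list", length(p$dilations))
  for (l in seq_along(p$dilations)) {
    inp <- if (length(sets[[l]]) == 0L) x0 else op_cat_c(c(list(x0), outs[sets[[l]]]))
    outs[[l]] <- fw_cbr(inp, p$layers[[l]]$conv, p$layers[[l]]$bn, training)
  }
  fw_cbr(op_cat_c(c(list(x0), outs)), p$proj, p$proj_bn, training)
}

# Interpolation matrix for exact 2x bilinear upsampling along one axis
# (half-pixel centres, edge-clamped). Row o of the (2n x n) matrix holds the
# weights of output position o over the input positions.
upsample2_matrix <- function(n) {
  A <- matrix(0, 2L * n, n)
  for (o in seq_len(2L * n)) {
    ci <- o / 2 + 0.25            # input-index coordinate of output centre
    l <- floor(ci)
    f <- ci - l
    l0 <- min(max(l, 1L), n)
    l1 <- min(l + 1L, n)
    if (l < 1L) {
      A[o, 1L] <- 1
    } else {
      A[o, l0] <- A[o, l0] + (1 - f)
      A[o, l1] <- A[o, l1] + f
    }
  }
  A
}

# apply a linear map along the height axis: (N,C,H,W) -> (N,C,nrow(A),W)
map_axis_h <- function(v, A) {
  d <- dim(v)
  xp <- aperm(v, c(1, 2, 4, 3))                       # (N,C,W,H)
  m <- matrix(xp, ncol = d[3]) %*% t(A)               # (N*C*W, Hout)
  aperm(array(m, c(d[1], d[2], d[4], nrow(A))), c(1, 2, 4, 3))
}

map_axis_w <- function(v, A) {
  d <- dim(v)
  m <- matrix(v, ncol = d[4]) %*% t(A)                # (N*C*H, Wout)
  array(m, c(d[1], d[2], d[3], nrow(A)))
}

# fixed (parameter-free) 2x bilinear upsampling used by the alternative decoder
op_upsample2_bilinear <- function(x) {
  d <- dim(x$v)
  AH <- upsample2_matrix(d[3])
  AW <- upsample2_matrix(d[4])
  y <- map_axis_w(map_axis_h(x$v, AH), AW)
  ag_node(y, list(x), function(g) {
    if (node_needs_grad(x)) {
      ag_accum(x, map_axis_h(map_axis_w(g, t(AW)), t(AH)))
    }
  })
}

#' Build an SCDU-Net model
#'
#' Assembles the full network: `stages` encoder stages of
#' \[cascaded residual stage -> spatial-channel attention -> stride-2
#' downsampling convolution\], a dense atrous pyramid pooling bottleneck,
#' and a symmetric decoder with skip connections tapped after the attention
#' block of each encoder stage. A 1x1 head maps to class logits.
#'
#' @param config A [network_config()].
#' @return An object of class `scdunet_model` (an environment holding the
#'   parameter tree, running batch-norm statistics and the config).
#' @export
build_scdunet <- function(config = network_config()) {
  stopifnot(inherits(config, "scdunet_config"))
  set.seed(config$seed)
  S <- config$stages
  b <- config$base_channels
  widths <- b * 2L^(seq_len(S) - 1L)
  enc_attn <- config$sc_placement %in% c("encoder", "both")
  dec_attn <- config$sc_placement %in% c("decoder", "both")

  enc <- lapply(seq_len(S), function(s) {
    Ci <- if (s == 1L) config$in_channels else widths[s]
    list(res = new_resstage(Ci, widths[s]),
         att = if (enc_attn) new_sc(widths[s], config$reduction) else NULL,
         down = new_conv(widths[s], widths[s] * 2L, 3L, stride = 2L, pad = 1L),
         down_bn = new_bn(widths[s] * 2L))
  })
  C0 <- b * 2L^S
  aspp <- new_denseaspp(C0, config$aspp_growth, config$aspp_dilations)
  dec <- lapply(rev(seq_len(S)), function(s) {
    Cin <- widths[s] * 2L
    Cout <- widths[s]
    up <- if (config$upsample == "transposed") new_convt(Cin, Cout) else new_conv(Cin, Cout, 3L, bias = TRUE)
    list(up = up,
         conv1 = new_conv(2L * Cout, Cout, 3L), bn1 = new_bn(Cout),
         conv2 = new_conv(Cout, Cout, 3L), bn2 = new_bn(Cout),
         att = if (dec_attn) new_sc(Cout, config$reduction) else NULL)
  })
  head <- new_conv(b, config$num_classes, 1L, bias = TRUE)

  model <- new.env(parent = emptyenv())
  model$config <- config
  model$pars <- list(enc = enc, aspp = aspp, dec = dec, head = head)
  class(model) <- "scdunet_model"
  model
}

# flatten the parameter tree into a named list of ag leaves
model_parameters <- function(model) {
  out <- list()
  walk <- function(x, path) {
    if (ag_is_node(x)) {
      out[[path]] <<- x
    } else if (is.list(x)) {
      nm <- names(x)
      for (i in seq_along(x)) {
        if (is.null(x[[i]])) next
        p <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else as.character(i)
        walk(x[[i]], paste(path, p, sep = "."))
      }
    }
  }
  walk(model$pars, "par")
  out
}

# all batch-norm state environments, for checkpointing
model_bn_states <- function(model) {
  out <- list()
  walk <- function(x, path) {
    if (is.environment(x) && !ag_is_node(x)) {
      out[[path]] <<- x
    } else if (is.list(x)) {
      nm <- names(x)
      for (i in seq_along(x)) {
        if (is.null(x[[i]])) next
        p <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else as.character(i)
        walk(x[[i]], paste(path, p, sep = "."))
      }
    }
  }
  walk(model$pars, "bn")
  out
}

#' Forward pass through an SCDU-Net model
#'
#' @param model A model from [build_scdunet()].
#' @param x Input batch, a numeric array of dim `(N, in_channels, H, W)`
#'   with `H` and `W` divisible by `2^stages`.
#' @param training Use batch statistics (and update running statistics) in
#'   batch-norm layers; `FALSE` gives a deterministic inference pass.
#' @return Logits array of dim `(N, num_classes, H, W)`.
#' @export
scdunet_forward <- function(model, x, training = FALSE) {
  out <- scdunet_forward_node(model, ag_leaf(x), training = training)
  out$result$v
}

# internal: returns list(result = logits node, tape, skips) so the training
# loop can run the backward sweep
scdunet_forward_node <- function(model, x, training = FALSE) {
  cfg <- model$config
  d <- dim(x$v)
  if (length(d) != 4L || d[2] != cfg$in_channels) {
    stop("input must be (N, ", cfg$in_channels, ", H, W)")
  }
  if (d[3] %% 2L^cfg$stages != 0L || d[4] %% 2L^cfg$stages != 0L) {
    stop("spatial size ", d[3], "x", d[4], " is not divisible by 2^",
         cfg$stages, " = ", 2L^cfg$stages)
  }
  ag_record({
    h <- x
    skips <- vector("list", cfg$stages)
    for (s in seq_len(cfg$stages)) {
      st <- model$pars$enc[[s]]
      h <- fw_resstage(h, st$res, training)
      if (!is.null(st$att)) h <- fw_sc(h, st$att)
      skips[[s]] <- h
      h <- fw_cbr(h, st$down, st$down_bn, training)
    }
    h <- fw_denseaspp(h, model$pars$aspp, training)
    for (i in seq_len(cfg$stages)) {
      s <- cfg$stages - i + 1L
      dc <- model$pars$dec[[i]]
      h <- if (cfg$upsample == "transposed") {
        op_convt2d(h, dc$up$w, dc$up$b, dc$up$stride)
      } else {
        fw_conv(op_upsample2_bilinear(h), dc$up)
      }
      h <- op_cat_c(list(h, skips[[s]]))
      h <- fw_cbr(h, dc$conv1, dc$bn1, training)
      h <- fw_cbr(h, dc$conv2, dc$bn2, training)
      if (!is.null(dc$att)) h <- fw_sc(h, dc$att)
    }
    fw_conv(h, model$pars$head)
  })
}

#' Count learnable convolutions on the encoder path
#'
#' Counting convention: each encoder stage contributes the four 3x3
#' convolutions of its two residual blocks plus the stride-2 downsampling
#' convolution (attention-branch 1x1 projections are not part of the
#' convolutional path). The default four-stage encoder is therefore 20
#' convolution layers deep.
#'
#' @param config A [network_config()].
#' @return Integer number of encoder convolution layers.
#' @export
encoder_conv_count <- function(config = network_config()) {
  stopifnot(inherits(config, "scdunet_config"))
  5L * config$stages
}
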