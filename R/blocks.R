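# Standalone forward passes for the individual network blocks, operating on
# plain (N,C,H,W) arrays in inference mode. These share the internal layer
# code with the full model; parameter bundles come from the init_* helpers.

as_feature_map <- function(x) {
  if (!is.array(x) || length(dim(x)) != 4L) {
    stop("a feature map must be a 4-axis array (batch, channel, height, width)")
  }
  if (any(dim(x) < 1L)) stop("all feature-map dimensions must be >= 1")
  if (!all(is.finite(x))) stop("feature-map values must be finite")
  x
}

run_eval <- function(expr) ag_value(force(expr)$result)

#' Initialise parameters for a cascaded residual stage
#'
#' Two residual blocks in series; each block is two 3x3
#' convolution/batch-norm/ReLU layers plus an identity shortcut
#' (`x' = x + F1(x) + F2(x + F1(x))`). When `in_channels != channels` the
#' first block uses a 1x1 projection shortcut.
#'
#' @param channels Stage width.
#' @param in_channels Input channels (default `channels`).
#' @param seed Weight-initialisation seed.
#' @return Parameter bundle for [residual_stage_forward()].
#' @export
init_residual_stage <- function(channels, in_channels = channels, seed = 1L) {
  set.seed(seed)
  new_resstage(as.integer(in_channels), as.integer(channels))
}

#' Cascaded residual stage forward pass
#'
#' @param x Feature map array `(N,C,H,W)`.
#' @param params From [init_residual_stage()].
#' @return Feature map of the same spatial size.
#' @export
residual_stage_forward <- function(x, params) {
  x <- as_feature_map(x)
  run_eval(ag_record(fw_resstage(ag_leaf(x), params, training = FALSE)))
}

#' Initialise channel (squeeze-and-excitation) attention parameters
#'
#' @param channels Number of channels `C`.
#' @param reduction Reduction ratio `r`; the bottleneck width is
#'   `max(4, floor(C/r))`.
#' @param seed Weight-initialisation seed.
#' @export
init_channel_attention <- function(channels, reduction = 16L, seed = 1L) {
  set.seed(seed)
  new_cse(as.integer(channels), as.integer(reduction))
}

#' Channel attention (cSE) forward pass
#'
#' Per-channel global average pooling, a two-layer bottleneck MLP
#' (ReLU then sigmoid), and broadcast channel re-weighting.
#'
#' @param x Feature map array `(N,C,H,W)`.
#' @param params From [init_channel_attention()].
#' @export
channel_attention_forward <- function(x, params) {
  x <- as_feature_map(x)
  run_eval(ag_record(fw_cse(ag_leaf(x), params)))
}

#' Initialise coordinate attention parameters
#'
#' @inheritParams init_channel_attention
#' @export
init_coordinate_attention <- function(channels, reduction = 16L, seed = 1L) {
  set.seed(seed)
  new_ca(as.integer(channels), as.integer(reduction))
}

#' Coordinate attention (CA) forward pass
#'
#' Directional average pools over width and height are concatenated along
#' the positional axis, passed through a shared 1x1 convolution with ReLU,
#' split back into the two directions, and mapped by per-branch 1x1
#' convolutions with sigmoid into gates `alpha_h` (length H) and `alpha_w`
#' (length W); the output is `x` gated by their outer broadcast product.
#'
#' @param x Feature map array `(N,C,H,W)`.
#' @param params From [init_coordinate_attention()].
#' @export
coordinate_attention_forward <- function(x, params) {
  x <- as_feature_map(x)
  run_eval(ag_record(fw_ca(ag_leaf(x), params)))
}

#' Initialise the fused spatial-channel attention block
#'
#' @inheritParams init_channel_attention
#' @export
init_sc_attention <- function(channels, reduction = 16L, seed = 1L) {
  set.seed(seed)
  new_sc(as.integer(channels), as.integer(reduction))
}

#' Spatial-channel (SC) dual attention forward pass
#'
#' Element-wise sum of the channel-attention and coordinate-attention
#' branch outputs.
#'
#' @param x Feature map array `(N,C,H,W)`.
#' @param params From [init_sc_attention()].
#' @export
sc_attention_forward <- function(x, params) {
  x <- as_feature_map(x)
  run_eval(ag_record(fw_sc(ag_leaf(x), params)))
}

#' Selective connectivity of the dense atrous pyramid
#'
#' For strictly increasing dilation rates, layer `l` consumes the original
#' input plus the outputs of every layer with a strictly smaller dilation:
#' `S_l = { i : d_i < d_l }`.
#'
#' @param dilations Strictly increasing positive integer dilation rates.
#' @return A `dilation_schedule` list with `dilations` and `input_sets`
#'   (one integer vector of layer indices per layer).
#' @export
denseaspp_input_sets <- function(dilations) {
  dilations <- as.integer(dilations)
  if (length(dilations) < 1L || any(dilations < 1L)) {
    stop("dilation rates must be positive integers")
  }
  if (any(diff(dilations) <= 0L)) {
    stop("dilation rates must be strictly increasing: a layer whose dilation ",
         "does not exceed an earlier one would need an input that is not ",
         "yet determined under sequential processing")
  }
  sets <- lapply(seq_along(dilations), function(l) which(dilations < dilations[l]))
  structure(list(dilations = dilations, input_sets = sets),
            class = "dilation_schedule")
}

#' Initialise dense atrous spatial pyramid pooling parameters
#'
#' @param channels Bottleneck channel count `C0`.
#' @param growth Channels produced by each dilated branch.
#' @param dilations Strictly increasing dilation rates.
#' @param seed Weight-initialisation seed.
#' @export
init_denseaspp <- function(channels, growth = max(4L, channels %/% 4L),
                           dilations = c(1L, 2L, 3L), seed = 1L) {
  set.seed(seed)
  new_denseaspp(as.integer(channels), as.integer(growth), as.integer(dilations))
}

#' Dense atrous spatial pyramid pooling forward pass
#'
#' Each branch is a "same"-padded 3x3 convolution at its dilation rate
#' followed by batch-norm and ReLU, consuming the concatenation defined by
#' [denseaspp_input_sets()]; a final 1x1 projection maps the concatenation
#' of the input and all branch outputs back to the bottleneck width.
#'
#' @param x0 Bottleneck feature map array `(N,C0,H,W)`.
#' @param params From [init_denseaspp()].
#' @export
denseaspp_forward <- function(x0, params) {
  x0 <- as_feature_map(x0)
  run_eval(ag_record(fw_denseaspp(ag_leaf(x0), params, training = FALSE)))
}

#' Receptive field of a dilated convolution
#'
#' `RF = k + (k - 1)(d - 1)` for kernel size `k` and dilation rate `d`.
#'
#' @param k Odd kernel size, `>= 1`.
#' @param d Dilation rate, `>= 1`.
#' @return Receptive field size in pixels.
#' @export
dilated_receptive_field <- function(k, d) {
  if (k < 1 || d < 1) stop("kernel size and dilation must be positive")
  if (k %% 2 != 1) stop("kernel size must be odd")
  as.integer(k + (k - 1) * (d - 1))
}

#' Receptive field of two stacked convolutions
#'
#' `K = K1 + K2 - 1` for individual receptive fields `K1` and `K2`.
#'
#' @param K1,K2 Receptive fields of the stacked operations, `>= 1`.
#' @return Combined receptive field size in pixels.
#' @export
stacked_receptive_field <- function(K1, K2) {
  if (K1 < 1 || K2 < 1) stop("receptive fields must be positive")
  as.integer(K1 + K2 - 1)
}

#' Maximum theoretical receptive field of the dense atrous pyramid
#'
#' Each branch sees its own dilated field `RF = k + (k-1)(d-1)`
#' superimposed on the largest field among the branches it consumes
#' (those with strictly smaller dilation), combined with
#' `K = K1 + K2 - 1`. With kernel 3 and dilations 1, 2, 3 the branch
#' fields are 3/5/7 and the deepest superposition reaches 13.
#'
#' @param k Odd kernel size.
#' @param dilations Strictly increasing dilation rates.
#' @return Maximum receptive field in pixels.
#' @export
denseaspp_max_receptive_field <- function(k = 3L, dilations = c(1L, 2L, 3L)) {
  sched <- denseaspp_input_sets(dilations)
  R <- integer(length(dilations))
  for (l in seq_along(dilations)) {
    own <- dilated_receptive_field(k, dilations[l])
    upstream <- if (length(sched$input_sets[[l]]) == 0L) 1L else max(R[sched$input_sets[[l]]])
    R[l] <- stacked_receptive_field(upstream, own)
  }
  max(R)
}
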