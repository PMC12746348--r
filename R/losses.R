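# Focal loss, multi-class soft Dice loss, and their alpha-weighted
# combination, together with closed-form gradients with respect to the
# logits (the network backward pass starts from these).

#' Loss configuration
#'
#' @param gamma Focusing parameter of the focal term; `gamma = 0` reduces it
#'   to plain cross-entropy. Default 2.
#' @param alpha Mixing weight: `alpha * focal + (1 - alpha) * dice`.
#'   Default 0.7 (focal:dice = 0.7:0.3).
#' @param epsilon Smoothing term in the soft Dice ratio. Default 1e-8.
#' @param dice_classes Classes averaged by the Dice loss:
#'   `"foreground_only"` (default; the dominant background would dilute the
#'   imbalance correction) or `"all_classes"`.
#' @return A `loss_config` list.
#' @export
loss_config <- function(gamma = 2, alpha = 0.7, epsilon = 1e-8,
                        dice_classes = c("foreground_only", "all_classes")) {
  dice_classes <- match.arg(dice_classes)
  if (gamma < 0) stop("`gamma` must be nonnegative")
  if (alpha < 0 || alpha > 1) stop("`alpha` must lie in [0, 1]")
  if (epsilon <= 0) stop("`epsilon` must be positive")
  structure(list(gamma = gamma, alpha = alpha, epsilon = epsilon,
                 dice_classes = dice_classes), class = "loss_config")
}

#' Softmax over the channel axis
#'
#' @param logits Array `(N,C,H,W)`.
#' @return Probabilities of the same shape, summing to 1 over channels.
#' @export
softmax_channels <- function(logits) {
  d <- dim(logits)
  m <- matrix(aperm(logits, c(1, 3, 4, 2)), ncol = d[2])
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  e <- exp(m - mx)
  p <- e / rowSums(e)
  unchan_mat(p, d)
}

#' One-hot encode an integer label map
#'
#' @param target Integer array `(N,H,W)` with labels in `0..(C-1)`.
#' @param num_classes Number of classes `C`.
#' @return Array `(N,C,H,W)` of 0/1 indicators.
#' @export
one_hot <- function(target, num_classes) {
  d <- dim(target)
  if (length(d) != 3L) stop("target must be a 3-axis (N,H,W) label array")
  if (any(target < 0) || any(target >= num_classes)) {
    stop("target labels must lie in 0..", num_classes - 1L)
  }
  oh <- array(0, c(d[1], num_classes, d[2], d[3]))
  for (cl in seq_len(num_classes) - 1L) {
    plane <- oh[, cl + 1L, , , drop = FALSE]
    dim(plane) <- d
    plane[target == cl] <- 1
    oh[, cl + 1L, , ] <- plane
  }
  oh
}

check_logits_target <- function(logits, target) {
  dl <- dim(logits)
  dt <- dim(target)
  if (length(dl) != 4L) stop("logits must be a 4-axis (N,C,H,W) array")
  if (length(dt) != 3L || !all(dt == dl[-2])) {
    stop("target must be (N,H,W) matching the logits batch and spatial dims")
  }
  if (any(target < 0) || any(target >= dl[2])) {
    stop("target labels must lie in 0..", dl[2] - 1L,
         " (got a label >= number of classes)")
  }
  invisible(NULL)
}

# per-pixel true-class probability, shape (N,H,W)
true_class_prob <- function(probs, target) {
  d <- dim(probs)
  pm <- matrix(aperm(probs, c(1, 3, 4, 2)), ncol = d[2])
  pt <- pm[cbind(seq_len(nrow(pm)), as.vector(target) + 1L)]
  array(pt, dim(target))
}

#' Focal loss
#'
#' Per-pixel cross-entropy `CE = -log p_t` from softmax probabilities
#' (natural log), modulated by `(1 - p_t)^gamma` and averaged over all
#' pixels and the batch. With `gamma = 0` this is exactly the mean
#' cross-entropy.
#'
#' @param logits Array `(N,C,H,W)` of raw class scores.
#' @param target Integer array `(N,H,W)` with labels in `0..(C-1)`.
#' @param cfg A [loss_config()].
#' @return Nonnegative scalar.
#' @export
focal_loss <- function(logits, target, cfg = loss_config()) {
  check_logits_target(logits, target)
  probs <- softmax_channels(logits)
  pt <- pmax(true_class_prob(probs, target), 1e-12)
  ce <- -log(pt)
  mean((1 - pt)^cfg$gamma * ce)
}

# gradient of focal_loss with respect to the logits, same shape as logits
focal_loss_grad <- function(logits, target, cfg = loss_config()) {
  d <- dim(logits)
  probs <- softmax_channels(logits)
  pt <- pmax(true_class_prob(probs, target), 1e-12)
  M <- prod(d[-2])
  if (cfg$gamma == 0) {
    coef <- array(-1, dim(pt))
  } else {
    om <- pmax(1 - pt, 1e-12)
    dfdp <- cfg$gamma * om^(cfg$gamma - 1) * log(pt) - om^cfg$gamma / pt
    coef <- dfdp * pt
  }
  oh <- one_hot(target, d[2])
  ce <- expand_to_dim(array(coef, c(d[1], 1L, d[3], d[4])), d)
  ce * (oh - probs) / M
}

#' Per-class soft Dice coefficients
#'
#' For class `c`: `(2 * sum(p_c * t_c) + eps) / (sum(p_c) + sum(t_c) + eps)`,
#' with sums over all pixels and the batch.
#'
#' @param probs Softmax probabilities `(N,C,H,W)`.
#' @param target_onehot One-hot target `(N,C,H,W)`.
#' @param cfg A [loss_config()] (supplies `epsilon`).
#' @return Numeric vector of length `C`, each value in `(0, 1]`.
#' @export
dice_coefficient_per_class <- function(probs, target_onehot, cfg = loss_config()) {
  if (!all(dim(probs) == dim(target_onehot))) {
    stop("probs and target_onehot must have identical (N,C,H,W) shapes")
  }
  C <- dim(probs)[2]
  pm <- matrix(aperm(probs, c(1, 3, 4, 2)), ncol = C)
  tm <- matrix(aperm(target_onehot, c(1, 3, 4, 2)), ncol = C)
  num <- 2 * colSums(pm * tm) + cfg$epsilon
  den <- colSums(pm) + colSums(tm) + cfg$epsilon
  num / den
}

dice_class_index <- function(C, cfg) {
  if (cfg$dice_classes == "foreground_only") {
    if (C < 2L) stop("foreground_only Dice needs at least 2 classes")
    2:C
  } else {
    seq_len(C)
  }
}

#' Soft Dice loss
#'
#' `1 -` mean of the per-class Dice coefficients over the selected classes
#' (foreground classes only by default).
#'
#' @inheritParams dice_coefficient_per_class
#' @return Scalar in `[0, 1]` up to the epsilon smoothing.
#' @export
dice_loss <- function(probs, target_onehot, cfg = loss_config()) {
  C <- dim(probs)[2]
  sel <- dice_class_index(C, cfg)
  dsc <- dice_coefficient_per_class(probs, target_onehot, cfg)
  1 - mean(dsc[sel])
}

# gradient of dice_loss with respect to the logits
dice_loss_grad <- function(logits, target, cfg = loss_config()) {
  d <- dim(logits)
  C <- d[2]
  probs <- softmax_channels(logits)
  oh <- one_hot(target, C)
  sel <- dice_class_index(C, cfg)
  pm <- matrix(aperm(probs, c(1, 3, 4, 2)), ncol = C)
  tm <- matrix(aperm(oh, c(1, 3, 4, 2)), ncol = C)
  num <- 2 * colSums(pm * tm) + cfg$epsilon
  den <- colSums(pm) + colSums(tm) + cfg$epsilon
  # dLoss/dp_c(i) = -(1/|sel|) * (2 t_c(i) den_c - num_c) / den_c^2, c in sel
  dLdp <- matrix(0, nrow(pm), C)
  for (cl in sel) {
    dLdp[, cl] <- -(2 * tm[, cl] * den[cl] - num[cl]) / (den[cl]^2 * length(sel))
  }
  # chain through softmax: dL/dz_k = p_k (dL/dp_k - sum_c dL/dp_c p_c)
  inner <- rowSums(dLdp * pm)
  gz <- pm * (dLdp - inner)
  unchan_mat(gz, d)
}

#' Combined focal/Dice loss
#'
#' `alpha * focal + (1 - alpha) * dice`, exactly affine in `alpha`.
#'
#' @inheritParams focal_loss
#' @return Scalar loss value.
#' @export
combined_loss <- function(logits, target, cfg = loss_config()) {
  combined_loss_parts(logits, target, cfg)$combined
}

# value of all three losses at once (shared softmax)
combined_loss_parts <- function(logits, target, cfg = loss_config()) {
  check_logits_target(logits, target)
  probs <- softmax_channels(logits)
  pt <- pmax(true_class_prob(probs, target), 1e-12)
  focal <- mean((1 - pt)^cfg$gamma * -log(pt))
  dice <- dice_loss(probs, one_hot(target, dim(logits)[2]), cfg)
  list(combined = cfg$alpha * focal + (1 - cfg$alpha) * dice,
       focal = focal, dice = dice)
}

# loss value and gradient with respect to logits, for the training loop
combined_loss_with_grad <- function(logits, target, cfg = loss_config()) {
  parts <- combined_loss_parts(logits, target, cfg)
  g <- cfg$alpha * focal_loss_grad(logits, target, cfg) +
    (1 - cfg$alpha) * dice_loss_grad(logits, target, cfg)
  c(parts, list(grad = g))
}
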