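# Experiment orchestration: Adam with cosine-annealed learning rate,
# early stopping on validation foreground Dice, five-fold cross-validation,
# and whole-volume inference from per-slice predictions.

#' Training configuration
#'
#' Defaults follow the full-scale protocol (Adam at 1e-4, batch 16, up to
#' 1000 epochs, cosine annealing from 1e-4 to a 1e-5 floor over 10000
#' batches, early stopping with 20-epoch patience). `preset = "test"`
#' switches to the fast suite preset: 64x64 slices, 8 base channels,
#' batch 4, and a larger step size suited to the short schedule.
#'
#' @param learning_rate Initial Adam learning rate.
#' @param batch_size Training batch size.
#' @param max_epochs Upper bound on epochs.
#' @param lr_floor Cosine annealing floor.
#' @param lr_period Annealing period in optimiser steps (batches).
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping.
#' @param seed Seed controlling weight init, slice shuffling and batching.
#' @param side Square slice size fed to the network.
#' @param network A [network_config()].
#' @param loss A [loss_config()].
#' @param preset `"full"` (default) or `"test"`.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 16L,
                         max_epochs = 1000L, lr_floor = 1e-5,
                         lr_period = 10000L, early_stop_patience = 20L,
                         seed = 1L, side = 448L,
                         network = network_config(),
                         loss = loss_config(),
                         preset = c("full", "test")) {
  preset <- match.arg(preset)
  if (preset == "test") {
    if (missing(side)) side <- 64L
    if (missing(batch_size)) batch_size <- 4L
    if (missing(learning_rate)) learning_rate <- 3e-3
    if (missing(network)) network <- network_config(base_channels = 8L, seed = seed)
  }
  if (learning_rate <= 0 || batch_size < 1L || max_epochs < 1L) {
    stop("rates and sizes must be positive")
  }
  if (early_stop_patience < 1L) stop("`early_stop_patience` must be >= 1")
  if (lr_floor < 0 || lr_floor > learning_rate) {
    stop("`lr_floor` must lie in [0, learning_rate]")
  }
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 lr_floor = lr_floor, lr_period = as.integer(lr_period),
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed), side = as.integer(side),
                 network = network, loss = loss, preset = preset),
            class = "train_config")
}

#' Cosine-annealed learning rate
#'
#' Starts at `base`, decays along a half cosine to `floor` at `period`
#' steps, and stays at the floor afterwards.
#'
#' @param step Optimiser step (1-based).
#' @param base,floor Initial and final learning rates.
#' @param period Annealing period in steps.
#' @return Learning rate for this step.
#' @export
cosine_lr <- function(step, base = 1e-4, floor = 1e-5, period = 10000L) {
  t <- pmin(pmax(step - 1, 0), period) / period
  floor + 0.5 * (base - floor) * (1 + cos(pi * t))
}

#' Early-stopping decision over a validation history
#'
#' @param scores Per-epoch validation scores (higher is better).
#' @param patience Consecutive non-improving epochs tolerated.
#' @param tol Minimum improvement that counts.
#' @return List with `stop_epoch` (first epoch at which training stops, or
#'   `NA` if never) and `best_epoch`.
#' @export
early_stop_epoch <- function(scores, patience = 20L, tol = 1e-6) {
  best <- 1L
  for (e in seq_along(scores)) {
    if (e > 1L && scores[e] > scores[best] + tol) best <- e
    if (e - best >= patience) {
      return(list(stop_epoch = e, best_epoch = best))
    }
  }
  list(stop_epoch = NA_integer_, best_epoch = best)
}

# ---- optimiser -------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(as.array(p$v)))),
       v = lapply(params, function(p) array(0, dim(as.array(p$v)))),
       t = 0L)
}

adam_step <- function(params, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(params)) {
    p <- params[[nm]]
    if (is.null(p$g)) next
    g <- p$g
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    p$v <- p$v - lr * (state$m[[nm]] / b1t) / (sqrt(state$v[[nm]] / b2t) + eps)
  }
  state
}

# ---- snapshots and checkpoints --------------------------------------------

model_snapshot <- function(model) {
  params <- model_parameters(model)
  bns <- model_bn_states(model)
  list(params = lapply(params, function(p) p$v),
       bn = lapply(bns, function(s) list(rm = s$rm, rv = s$rv)))
}

model_restore <- function(model, snap) {
  params <- model_parameters(model)
  for (nm in names(snap$params)) params[[nm]]$v <- snap$params[[nm]]
  bns <- model_bn_states(model)
  for (nm in names(snap$bn)) {
    bns[[nm]]$rm <- snap$bn[[nm]]$rm
    bns[[nm]]$rv <- snap$bn[[nm]]$rv
  }
  invisible(model)
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores the full network configuration alongside the
#' weights and batch-norm running statistics.
#'
#' @param model An `scdunet_model`.
#' @param path Checkpoint file path (RDS).
#' @return `save_checkpoint`: the path, invisibly. `load_checkpoint`: a
#'   rebuilt `scdunet_model`.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = model$config, snapshot = model_snapshot(model)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_scdunet(ck$config)
  model_restore(model, ck$snapshot)
  model
}

# ---- data assembly ---------------------------------------------------------

resize_image <- function(img, side) {
  if (all(dim(img) == c(side, side))) return(img)
  matrix(as.numeric(EBImage::resize(img, w = side, h = side, filter = "bilinear")),
         side, side)
}

# screened, normalised, resampled training slices for a set of cases
build_slice_dataset <- function(cases, ids, side) {
  images <- list()
  masks <- list()
  for (id in ids) {
    cs <- cases[[id]]
    voln <- normalize_intensity(cs$volume)
    for (k in screen_slices(cs)) {
      rs <- resample_slice(voln[, , k], cs$mask[, , k], side)
      images[[length(images) + 1L]] <- rs$image
      masks[[length(masks) + 1L]] <- rs$mask
    }
  }
  list(images = images, masks = masks)
}

assemble_batch <- function(ds, idx, side) {
  n <- length(idx)
  x <- array(0, c(n, 1L, side, side))
  y <- array(0L, c(n, side, side))
  for (i in seq_len(n)) {
    x[i, 1L, , ] <- ds$images[[idx[i]]]
    y[i, , ] <- ds$masks[[idx[i]]]
  }
  list(x = x, y = y)
}

# ---- inference -------------------------------------------------------------

#' Predict a label volume for one case
#'
#' Every axial slice (no screening) is normalised, resized to the network
#' side, passed through the model in inference mode, argmaxed over the
#' class logits, and resized back to the native in-plane shape with
#' nearest-neighbour interpolation.
#'
#' @param model An `scdunet_model` or a checkpoint path.
#' @param case An `mri_case`.
#' @param side Network input side length.
#' @param batch_slices Number of slices per forward pass.
#' @return Integer label volume with the shape of `case$mask`.
#' @export
predict_volume <- function(model, case, side = 448L, batch_slices = 8L) {
  if (is.character(model)) model <- load_checkpoint(model)
  stopifnot(inherits(model, "scdunet_model"), inherits(case, "mri_case"))
  d <- dim(case$volume)
  voln <- normalize_intensity(case$volume)
  nz <- d[3]
  pred <- array(0L, d)
  for (start in seq(1L, nz, by = batch_slices)) {
    ks <- start:min(start + batch_slices - 1L, nz)
    x <- array(0, c(length(ks), 1L, side, side))
    for (i in seq_along(ks)) x[i, 1L, , ] <- resize_image(voln[, , ks[i]], side)
    logits <- scdunet_forward(model, x, training = FALSE)
    C <- dim(logits)[2]
    pm <- matrix(aperm(logits, c(1, 3, 4, 2)), ncol = C)
    lab <- array(max.col(pm, ties.method = "first") - 1L,
                 c(length(ks), side, side))
    for (i in seq_along(ks)) {
      sl <- matrix(lab[i, , ], side, side)
      if (!all(d[1:2] == side)) {
        sl <- matrix(as.integer(EBImage::resize(sl, w = d[1], h = d[2],
                                                filter = "none")), d[1], d[2])
      }
      pred[, , ks[i]] <- sl
    }
  }
  pred
}

# mean foreground DSC of a model over a list of validation cases
validation_foreground_dsc <- function(model, cases, ids, side) {
  scores <- vapply(ids, function(id) {
    cs <- cases[[id]]
    pred <- predict_volume(model, cs, side = side)
    ev <- evaluate_volume(cs$mask, pred, cs$spacing_mm, cs$case_id)
    mean(ev$dsc[ev$structure != "avg"], na.rm = TRUE)
  }, numeric(1))
  mean(scores, na.rm = TRUE)
}

# ---- training --------------------------------------------------------------

#' Train one cross-validation fold
#'
#' Trains on the screened lesion slices of the fold's training cases with
#' the combined focal/Dice loss, evaluates the full validation volumes
#' after every epoch (mean foreground DSC), keeps the best-validation
#' weights, and stops early after `early_stop_patience` epochs without
#' improvement. Fully seeded: identical config and data give identical
#' runs.
#'
#' @param fold A `list(train = ids, val = ids)` fold entry.
#' @param cfg A [train_config()].
#' @param cases Named list of `mri_case` objects, or a directory of paired
#'   NIfTI files.
#' @param verbose Print per-epoch progress lines.
#' @return List with `model` (best weights), `history` (per-epoch
#'   data.frame: epoch, train_loss, val_dsc, lr), `best_epoch`,
#'   `stopped` (`"early_stopping"` or `"max_epochs"`).
#' @export
train_fold <- function(fold, cfg = train_config(), cases, verbose = FALSE) {
  if (is.character(cases)) cases <- read_cohort(cases)
  missing_ids <- setdiff(c(fold$train, fold$val), names(cases))
  if (length(missing_ids) > 0) {
    stop("missing case files for ids: ", paste(missing_ids, collapse = ", "))
  }
  model <- build_scdunet(cfg$network)
  params <- model_parameters(model)
  opt <- adam_init(params)
  set.seed(cfg$seed)
  ds <- build_slice_dataset(cases, fold$train, cfg$side)
  n_slices <- length(ds$images)
  if (n_slices == 0L) stop("no lesion slices found in the training cases")

  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_dsc = numeric(), lr = numeric())
  best_score <- -Inf
  best_epoch <- 0L
  best_snap <- NULL
  step <- 0L
  stopped <- "max_epochs"

  for (epoch in seq_len(cfg$max_epochs)) {
    perm <- sample(n_slices)
    losses <- numeric(0)
    lr <- cfg$learning_rate
    for (start in seq(1L, n_slices, by = cfg$batch_size)) {
      idx <- perm[start:min(start + cfg$batch_size - 1L, n_slices)]
      batch <- assemble_batch(ds, idx, cfg$side)
      fwd <- scdunet_forward_node(model, ag_leaf(batch$x), training = TRUE)
      lw <- combined_loss_with_grad(fwd$result$v, batch$y, cfg$loss)
      ag_backward(fwd$result, lw$grad, fwd$tape)
      step <- step + 1L
      lr <- cosine_lr(step, cfg$learning_rate, cfg$lr_floor, cfg$lr_period)
      opt <- adam_step(params, opt, lr)
      ag_zero_grad(params)
      losses <- c(losses, lw$combined)
    }
    val <- validation_foreground_dsc(model, cases, fold$val, cfg$side)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(losses),
                                         val_dsc = val, lr = lr))
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val_dsc %.4f  lr %.2e",
                      epoch, mean(losses), val, lr))
    }
    if (is.finite(val) && val > best_score + 1e-6) {
      best_score <- val
      best_epoch <- epoch
      best_snap <- model_snapshot(model)
    }
    if (epoch - best_epoch >= cfg$early_stop_patience) {
      stopped <- "early_stopping"
      break
    }
  }
  if (!is.null(best_snap)) model_restore(model, best_snap)
  list(model = model, history = history, best_epoch = best_epoch,
       stopped = stopped)
}

#' Five-fold cross-validation
#'
#' Runs [train_fold()] for every fold of the plan, evaluates each fold's
#' validation cases, and reports per-fold and averaged metrics in a
#' fold-by-fold column layout.
#'
#' @param plan A `fold_plan` from [make_fold_plan()].
#' @param cfg A [train_config()].
#' @param cases Named list of `mri_case` objects or a directory.
#' @param verbose Print progress.
#' @return List with `table` (rows: metric; columns: Fold0..FoldK,
#'   Average), `reports` (per-fold [metric_report()]s) and `fits`
#'   (per-fold training results).
#' @export
cross_validate <- function(plan, cfg = train_config(), cases, verbose = FALSE) {
  stopifnot(inherits(plan, "fold_plan"))
  if (is.character(cases)) cases <- read_cohort(cases)
  fits <- list()
  reports <- list()
  for (k in seq_along(plan$folds)) {
    if (verbose) message("fold ", k - 1L)
    fold <- plan$folds[[k]]
    fit <- train_fold(fold, cfg, cases, verbose = verbose)
    preds <- lapply(fold$val, function(id) {
      predict_volume(fit$model, cases[[id]], side = cfg$side)
    })
    gts <- lapply(fold$val, function(id) cases[[id]]$mask)
    spacings <- lapply(fold$val, function(id) cases[[id]]$spacing_mm)
    reports[[k]] <- metric_report(gts, preds, spacings, fold$val)
    fits[[k]] <- fit
  }
  dsc <- vapply(reports, function(r) r$averages$mean_dsc, numeric(1))
  hd <- vapply(reports, function(r) r$averages$mean_hd95_mm, numeric(1))
  tab <- data.frame(metric = c("dsc", "hd95_mm"),
                    stringsAsFactors = FALSE)
  for (k in seq_along(reports)) tab[[paste0("Fold", k - 1L)]] <- c(dsc[k], hd[k])
  tab$Average <- c(mean(dsc), mean(hd))
  list(table = tab, reports = reports, fits = fits)
}

#' Grid search over the focal/Dice mixing weight
#'
#' Trains one model per (alpha, fold) with the supplied training routine
#' and averages the validation metrics per alpha. The routine is expected
#' to honour the alpha it receives (toy-scale phantom training in this
#' package); results characterise the synthetic task only.
#'
#' @param train_fn `function(alpha, fold)` returning `list(dsc = , hd95 = )`.
#' @param alphas Mixing weights to evaluate (default 0, 0.1, ..., 1).
#' @param folds List of fold entries (`list(train, val)`).
#' @return `data.frame` with columns `alpha`, `dice_weight`, `mean_dsc`,
#'   `mean_hd95`, sorted by `alpha`.
#' @export
alpha_grid_search <- function(train_fn, alphas = seq(0, 1, by = 0.1), folds) {
  if (length(alphas) == 0L) stop("`alphas` must be a nonempty numeric vector")
  if (any(alphas < 0 | alphas > 1)) stop("alphas must lie in [0, 1]")
  rows <- lapply(sort(alphas), function(a) {
    res <- lapply(folds, function(f) train_fn(a, f))
    data.frame(alpha = a, dice_weight = 1 - a,
               mean_dsc = mean(vapply(res, function(r) r$dsc, numeric(1)),
                               na.rm = TRUE),
               mean_hd95 = mean(vapply(res, function(r) r$hd95, numeric(1)),
                                na.rm = TRUE))
  })
  do.call(rbind, rows)
}
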