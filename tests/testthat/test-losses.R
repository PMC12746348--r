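test_that("focal loss with gamma 0 is exactly mean cross-entropy", {
  set.seed(11)
  logits <- rand_fm(2, 3, 4, 4)
  target <- array(sample(0:2, 32, TRUE), c(2, 4, 4))
  cfg0 <- loss_config(gamma = 0)
  expect_equal(focal_loss(logits, target, cfg0),
               naive_focal(logits, target, gamma = 0), tolerance = 1e-12)
})

test_that("focal loss matches the per-pixel oracle and its worked value", {
  set.seed(12)
  logits <- rand_fm(2, 3, 4, 4)
  target <- array(sample(0:2, 32, TRUE), c(2, 4, 4))
  cfg <- loss_config(gamma = 2)
  expect_lt(abs(focal_loss(logits, target, cfg) -
                  naive_focal(logits, target, gamma = 2)), 1e-6)

  # one pixel, two equal logits: p_t = 0.5, CE = ln 2, focal = 0.25 ln 2
  lg <- array(0, c(1, 2, 1, 1))
  tg <- array(0L, c(1, 1, 1))
  expect_equal(focal_loss(lg, tg, cfg), 0.25 * log(2), tolerance = 1e-12)

  # near-perfect prediction drives the loss to zero
  lg[1, 1, 1, 1] <- 30
  expect_lt(focal_loss(lg, tg, cfg), 1e-10)

  # focusing never increases the loss relative to cross-entropy
  expect_lte(focal_loss(logits, target, cfg),
             focal_loss(logits, target, loss_config(gamma = 0)))

  expect_error(focal_loss(logits, array(5L, c(2, 4, 4)), cfg), "labels")
})

test_that("soft Dice coefficients reproduce worked overlap values", {
  cfg <- loss_config()
  # hard masks: |pred| = |gt| = 2 with overlap 1 in each foreground class
  probs <- array(0, c(1, 3, 4, 1))
  oh <- array(0, c(1, 3, 4, 1))
  probs[1, , 1, 1] <- c(0, 1, 0); oh[1, , 1, 1] <- c(0, 1, 0)  # overlap
  probs[1, , 2, 1] <- c(0, 1, 0); oh[1, , 2, 1] <- c(1, 0, 0)
  probs[1, , 3, 1] <- c(1, 0, 0); oh[1, , 3, 1] <- c(0, 1, 0)
  probs[1, , 4, 1] <- c(1, 0, 0); oh[1, , 4, 1] <- c(1, 0, 0)
  dsc <- dice_coefficient_per_class(probs, oh, cfg)
  expect_equal(dsc[2], 0.5, tolerance = 1e-7)   # 2*1/(2+2)

  # identical hard one-hot: Dice ~ 1 for present classes
  ident <- dice_coefficient_per_class(oh, oh, cfg)
  expect_equal(ident[1], 1, tolerance = 1e-7)
  expect_equal(ident[2], 1, tolerance = 1e-7)

  # fully disjoint foreground: epsilon-dominated Dice ~ 0
  a <- array(0, c(1, 2, 2, 1)); b <- array(0, c(1, 2, 2, 1))
  a[1, 2, 1, 1] <- 1; a[1, 1, 2, 1] <- 1
  b[1, 1, 1, 1] <- 1; b[1, 2, 2, 1] <- 1
  expect_lt(dice_coefficient_per_class(a, b, cfg)[2], 1e-7)

  set.seed(13)
  probs <- softmax_channels(rand_fm(2, 3, 4, 4))
  oh <- one_hot(array(sample(0:2, 32, TRUE), c(2, 4, 4)), 3L)
  expect_lt(max(abs(dice_coefficient_per_class(probs, oh, cfg) -
                      naive_dice_per_class(probs, oh, cfg$epsilon))), 1e-6)
})

test_that("dice loss averages the selected classes", {
  cfg <- loss_config()
  # two foreground classes with Dice 0.5 and 1.0 -> loss 0.25
  probs <- array(0, c(1, 3, 6, 1))
  oh <- array(0, c(1, 3, 6, 1))
  probs[1, , 1, 1] <- c(0, 1, 0); oh[1, , 1, 1] <- c(0, 1, 0)
  probs[1, , 2, 1] <- c(0, 1, 0); oh[1, , 2, 1] <- c(1, 0, 0)
  probs[1, , 3, 1] <- c(1, 0, 0); oh[1, , 3, 1] <- c(0, 1, 0)
  probs[1, , 4, 1] <- c(0, 0, 1); oh[1, , 4, 1] <- c(0, 0, 1)
  probs[1, , 5, 1] <- c(0, 0, 1); oh[1, , 5, 1] <- c(0, 0, 1)
  probs[1, , 6, 1] <- c(1, 0, 0); oh[1, , 6, 1] <- c(1, 0, 0)
  expect_equal(dice_loss(probs, oh, cfg), 0.25, tolerance = 1e-6)
  expect_lt(dice_loss(oh, oh, cfg), 1e-6)                     # perfect
  expect_error(dice_loss(array(1, c(1, 1, 2, 2)), array(1, c(1, 1, 2, 2)), cfg),
               "at least 2")
})

test_that("the combined loss is exactly affine in alpha", {
  set.seed(14)
  logits <- rand_fm(2, 3, 4, 4)
  target <- array(sample(0:2, 32, TRUE), c(2, 4, 4))
  f <- focal_loss(logits, target, loss_config(alpha = 1))
  d <- dice_loss(softmax_channels(logits), one_hot(target, 3L), loss_config())
  for (a in c(0, 0.25, 0.5, 0.7, 1)) {
    expect_equal(combined_loss(logits, target, loss_config(alpha = a)),
                 a * f + (1 - a) * d, tolerance = 1e-12)
  }
  expect_equal(combined_loss(logits, target, loss_config(alpha = 1)), f)
  expect_error(loss_config(alpha = 1.5), "\\[0, 1\\]")
  expect_error(loss_config(alpha = -0.1), "\\[0, 1\\]")
})

test_that("analytic loss gradients agree with finite differences", {
  set.seed(15)
  logits <- rand_fm(1, 3, 3, 3)
  target <- array(sample(0:2, 9, TRUE), c(1, 3, 3))
  cfg <- loss_config()
  lw <- scdunet:::combined_loss_with_grad(logits, target, cfg)
  expect_true(all(is.finite(lw$grad)))
  eps <- 1e-6
  for (ii in sample(length(logits), 8)) {
    pert <- logits
    pert[ii] <- pert[ii] + eps
    fd <- (combined_loss(pert, target, cfg) - lw$combined) / eps
    expect_equal(lw$grad[ii], fd, tolerance = 1e-4)
  }
})

test_that("the alpha grid search honours its protocol", {
  seen <- new.env(); seen$alphas <- numeric(0)
  spy <- function(alpha, fold) {
    seen$alphas <- c(seen$alphas, alpha)
    list(dsc = 0.5 + 0.1 * alpha, hd95 = 10 - alpha)
  }
  folds <- list(list(train = "a", val = "b"), list(train = "c", val = "d"))
  tab <- alpha_grid_search(spy, alphas = c(1, 0, 0.5), folds = folds)
  expect_equal(tab$alpha, c(0, 0.5, 1))               # sorted
  expect_equal(tab$dice_weight, 1 - tab$alpha)
  expect_true(all(is.finite(tab$mean_dsc)) && all(tab$mean_dsc >= 0 & tab$mean_dsc <= 1))
  expect_equal(sum(seen$alphas == 1), 2L)             # one run per fold at alpha 1
  expect_equal(nrow(alpha_grid_search(spy, folds = folds)), 11L)  # 0.1 spacing
  expect_error(alpha_grid_search(spy, alphas = numeric(0), folds = folds),
               "nonempty")
})
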