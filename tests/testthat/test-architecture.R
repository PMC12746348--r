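test_that("directional and global pooling follow their definitions", {
  # single-channel 2x3 map with rows [1,2,3] and [4,5,6]
  x <- array(0, c(1, 1, 2, 3))
  x[1, 1, 1, ] <- c(1, 2, 3)
  x[1, 1, 2, ] <- c(4, 5, 6)
  expect_equal(as.vector(scdunet:::op_pool_w(scdunet:::ag_leaf(x))$v), c(2, 5))
  expect_equal(as.vector(scdunet:::op_pool_h(scdunet:::ag_leaf(x))$v), c(2.5, 3.5, 4.5))

  ones <- array(1, c(1, 3, 4, 4))
  expect_equal(as.vector(scdunet:::op_gap(scdunet:::ag_leaf(ones))$v), rep(1, 3))
  q <- array(0, c(1, 1, 2, 2))
  q[1, 1, , ] <- matrix(c(1, 3, 2, 4), 2, 2)
  expect_equal(as.vector(scdunet:::op_gap(scdunet:::ag_leaf(q))$v), 2.5)
})

test_that("residual stages reduce to identity when the branches are zero", {
  params <- init_residual_stage(channels = 3L, seed = 2L)
  for (blk in params) {
    blk$conv1$w$v[] <- 0
    blk$conv2$w$v[] <- 0
  }
  x <- rand_fm(2, 3, 8, 8)
  expect_equal(residual_stage_forward(x, params), x, tolerance = 1e-12)
})

test_that("residual stages match the loop-based convolution oracle", {
  set.seed(31)
  params <- init_residual_stage(channels = 2L, seed = 31L)
  x <- rand_fm(1, 2, 8, 8)
  got <- residual_stage_forward(x, params)
  expect_equal(dim(got), dim(x))
  expect_lt(max(abs(got - naive_resstage(x, params))), 1e-5)

  # projection shortcut when input and stage channels differ
  p2 <- init_residual_stage(channels = 4L, in_channels = 2L, seed = 32L)
  got2 <- residual_stage_forward(x, p2)
  expect_equal(dim(got2), c(1L, 4L, 8L, 8L))
  expect_lt(max(abs(got2 - naive_resstage(x, p2))), 1e-5)
})

test_that("channel attention gates lie in (0,1) and match the oracle", {
  set.seed(41)
  p <- init_channel_attention(channels = 4L, reduction = 2L, seed = 41L)
  x <- rand_fm(2, 4, 8, 8)
  got <- channel_attention_forward(x, p)
  expect_lt(max(abs(got - naive_cse(x, p))), 1e-6)
  # gates recoverable as y/x where x != 0: strictly inside (0,1)
  gates <- got / x
  expect_true(all(gates > 0 & gates < 1))
})

test_that("coordinate attention matches the directional-pool oracle", {
  set.seed(42)
  p <- init_coordinate_attention(channels = 8L, reduction = 4L, seed = 42L)
  x <- rand_fm(1, 8, 6, 5)
  got <- coordinate_attention_forward(x, p)
  expect_equal(dim(got), dim(x))
  expect_lt(max(abs(got - naive_ca(x, p))), 1e-6)
  gates <- got / x
  expect_true(all(gates > 0 & gates < 1))
})

test_that("forcing all-ones gates makes attention a pass-through", {
  p <- init_coordinate_attention(channels = 3L, reduction = 2L, seed = 5L)
  # sigmoid(large positive bias) ~ 1 regardless of input
  p$convh$w$v[] <- 0; p$convh$b$v[] <- 50
  p$convw$w$v[] <- 0; p$convw$b$v[] <- 50
  x <- rand_fm(1, 3, 4, 4)
  expect_equal(coordinate_attention_forward(x, p), x, tolerance = 1e-8)

  pc <- init_channel_attention(channels = 3L, reduction = 2L, seed = 5L)
  pc$fc2$W$v[] <- 0; pc$fc2$b$v[] <- 50
  expect_equal(channel_attention_forward(x, pc), x, tolerance = 1e-8)

  # with both branches forced open, the fused block doubles its input
  sc <- list(cse = pc, ca = p)
  expect_equal(sc_attention_forward(x, sc), 2 * x, tolerance = 1e-7)
})

test_that("SC attention is exactly the sum of its two branches", {
  p <- init_sc_attention(channels = 4L, reduction = 2L, seed = 6L)
  x <- rand_fm(2, 4, 5, 7)
  fused <- sc_attention_forward(x, p)
  expect_equal(fused,
               channel_attention_forward(x, p$cse) +
                 coordinate_attention_forward(x, p$ca),
               tolerance = 1e-12)
  expect_lt(max(abs(fused - (naive_cse(x, p$cse) + naive_ca(x, p$ca)))), 1e-6)
})

test_that("dense pyramid connectivity follows the smaller-dilation rule", {
  sched <- denseaspp_input_sets(c(1, 2, 3))
  expect_equal(sched$input_sets, list(integer(0), 1L, c(1L, 2L)))
  expect_equal(denseaspp_input_sets(5)$input_sets, list(integer(0)))
  expect_error(denseaspp_input_sets(c(2, 2)), "strictly increasing")
  expect_error(denseaspp_input_sets(c(3, 1)), "strictly increasing")
  expect_error(denseaspp_input_sets(c(0, 1)), "positive")

  set.seed(77)
  for (i in 1:20) {
    dil <- sort(sample(1:40, sample(1:6, 1)))
    sched <- denseaspp_input_sets(dil)
    for (l in seq_along(dil)) {
      expect_identical(sched$input_sets[[l]], which(dil < dil[l]))
    }
    expect_length(sched$input_sets[[1]], 0L)
  }
})

test_that("dense pyramid channel arithmetic and spatial preservation hold", {
  p <- init_denseaspp(channels = 16L, growth = 4L, dilations = c(1, 2, 3), seed = 8L)
  # layer 3 consumes x0 plus two branch outputs: C0 + 2G input channels
  expect_equal(dim(p$layers[[3]]$conv$w$v)[2], 16L + 2L * 4L)
  x <- rand_fm(1, 16, 14, 14)
  got <- denseaspp_forward(x, p)
  expect_equal(dim(got), dim(x))
})

test_that("dense pyramid forward matches the naive dilated-convolution oracle", {
  set.seed(9)
  p <- init_denseaspp(channels = 6L, growth = 3L, dilations = c(1, 2, 3), seed = 9L)
  x <- rand_fm(1, 6, 10, 10)
  expect_lt(max(abs(denseaspp_forward(x, p) - naive_denseaspp(x, p))), 1e-5)
})

test_that("receptive-field algebra reproduces the printed branch fields", {
  expect_equal(dilated_receptive_field(3, 1), 3L)
  expect_equal(dilated_receptive_field(3, 2), 5L)
  expect_equal(dilated_receptive_field(3, 3), 7L)
  expect_equal(stacked_receptive_field(7, 7), 13L)
  expect_equal(stacked_receptive_field(1, 9), 9L)
  expect_equal(stacked_receptive_field(3, 5), 7L)
  expect_error(dilated_receptive_field(0, 1), "positive")
  expect_error(dilated_receptive_field(4, 1), "odd")
  expect_error(stacked_receptive_field(0, 3), "positive")
})

test_that("the assembled network maps inputs to class logits of the same size", {
  cfg <- network_config(base_channels = 4L, stages = 4L, seed = 3L)
  model <- build_scdunet(cfg)
  x <- rand_fm(1, 1, 64, 64)
  y <- scdunet_forward(model, x)
  expect_equal(dim(y), c(1L, 3L, 64L, 64L))
  expect_true(all(is.finite(y)))
  expect_identical(scdunet_forward(model, x), y)   # deterministic inference

  expect_error(scdunet_forward(model, rand_fm(1, 1, 60, 60)), "divisible")
  expect_error(scdunet_forward(model, rand_fm(1, 2, 64, 64)), "N, 1")
})

test_that("full-resolution inputs pass through the default-depth network", {
  cfg <- network_config(base_channels = 4L, stages = 4L, seed = 3L)
  model <- build_scdunet(cfg)
  y <- scdunet_forward(model, rand_fm(1, 1, 448, 448))
  expect_equal(dim(y), c(1L, 3L, 448L, 448L))
})

test_that("decoder placement and bilinear upsampling variants build and run", {
  for (cfg in list(network_config(base_channels = 4L, stages = 2L,
                                  sc_placement = "decoder", seed = 4L),
                   network_config(base_channels = 4L, stages = 2L,
                                  sc_placement = "both", seed = 4L),
                   network_config(base_channels = 4L, stages = 2L,
                                  upsample = "bilinear", seed = 4L))) {
    model <- build_scdunet(cfg)
    y <- scdunet_forward(model, rand_fm(1, 1, 16, 16))
    expect_equal(dim(y), c(1L, 3L, 16L, 16L))
  }
})

test_that("encoder depth counting matches the five-conv-per-stage convention", {
  expect_equal(encoder_conv_count(network_config()), 20L)
  expect_equal(encoder_conv_count(network_config(stages = 1L)), 5L)
  expect_error(network_config(stages = 0L), "stages")
})
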