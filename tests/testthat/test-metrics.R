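test_that("pairwise Dice follows its definition and empty-mask policy", {
  m <- array(FALSE, c(4, 4, 2)); m[1:3, 1, 1] <- TRUE
  expect_equal(dsc_pair(m, m), 1)

  gt <- array(FALSE, c(4, 4, 2)); gt[1:2, 1, 1] <- TRUE
  pr <- array(FALSE, c(4, 4, 2)); pr[2:3, 1, 1] <- TRUE
  expect_equal(dsc_pair(gt, pr), 0.5)                    # 2*1/(2+2)

  empty <- array(FALSE, c(4, 4, 2))
  expect_true(is.na(dsc_pair(empty, empty)))             # undefined, not 0/1
  expect_equal(dsc_pair(empty, pr), 0)
  expect_error(dsc_pair(m, array(FALSE, c(4, 4, 3))), "identical shapes")

  set.seed(21)
  for (i in 1:10) {
    a <- rand_mask(c(5, 5, 3)); b <- rand_mask(c(5, 5, 3))
    expect_identical(dsc_pair(a, b), dsc_pair(b, a))     # symmetry
  }
})

test_that("aggregated Dice pools counts before the ratio", {
  # case A: |gt| = |pred| = 10, overlap 5; case B: |gt| = |pred| = 2, overlap 2
  gA <- array(FALSE, c(10, 2, 1)); gA[1:10, 1, 1] <- TRUE
  pA <- array(FALSE, c(10, 2, 1)); pA[6:10, 1, 1] <- TRUE; pA[1:5, 2, 1] <- TRUE
  gB <- array(FALSE, c(10, 2, 1)); gB[1:2, 1, 1] <- TRUE
  pB <- gB
  expect_equal(dsc_pair(gA, pA), 0.5)
  expect_equal(dsc_pair(gB, pB), 1.0)
  expect_equal(dsc_agg(list(list(gt = gA, pred = pA), list(gt = gB, pred = pB))),
               14 / 24)

  one <- list(list(gt = gA, pred = pA))
  expect_identical(dsc_agg(one), dsc_pair(gA, pA))       # N = 1 reduction

  empty <- array(FALSE, c(3, 3, 1))
  expect_true(is.na(dsc_agg(list(list(gt = empty, pred = empty)))))
  expect_error(dsc_agg(list()), "nonempty")
})

test_that("aggregated Dice is the size-weighted mean of per-case Dice", {
  set.seed(22)
  for (i in 1:8) {
    pool <- lapply(1:4, function(j) list(gt = rand_mask(c(6, 6, 2), 0.2),
                                         pred = rand_mask(c(6, 6, 2), 0.2)))
    per <- vapply(pool, function(cs) dsc_pair(cs$gt, cs$pred), numeric(1))
    wts <- vapply(pool, function(cs) sum(cs$gt) + sum(cs$pred), numeric(1))
    agg <- dsc_agg(pool)
    keep <- !is.na(per)
    expect_equal(agg, sum(per[keep] * wts[keep]) / sum(wts[keep]), tolerance = 1e-12)
    expect_gte(agg, min(per, na.rm = TRUE) - 1e-12)
    expect_lte(agg, max(per, na.rm = TRUE) + 1e-12)
  }
})

test_that("Hausdorff distance equals the exhaustive max-min oracle", {
  expect_equal(hausdorff(matrix(c(1, 1, 1), 1), matrix(c(1, 1, 1), 1)), 0)
  # singleton sets 5 mm apart (10 voxels at 0.5 mm)
  expect_equal(hausdorff(matrix(c(0, 0, 0), 1), matrix(c(10, 0, 0), 1),
                         spacing_mm = c(0.5, 0.5, 2)), 5)
  expect_true(is.na(hausdorff(matrix(numeric(0), 0, 3), matrix(c(1, 1, 1), 1))))

  set.seed(23)
  for (i in 1:8) {
    P <- matrix(sample(0:20, 3 * sample(2:50, 1), TRUE), ncol = 3)
    Q <- matrix(sample(0:20, 3 * sample(2:50, 1), TRUE), ncol = 3)
    sp <- c(0.5, 0.5, 2)
    Pm <- sweep(P, 2, sp, `*`); Qm <- sweep(Q, 2, sp, `*`)
    expect_equal(hausdorff(P, Q, sp),
                 max(naive_directed_h(Pm, Qm), naive_directed_h(Qm, Pm)),
                 tolerance = 1e-12)
    expect_equal(hausdorff(P, Q, sp), hausdorff(Q, P, sp))   # symmetry
    # identity of indiscernibles on point sets
    expect_equal(hausdorff(P, P[sample(nrow(P)), , drop = FALSE], sp), 0)
    if (hausdorff(P, Q, sp) == 0) {
      expect_setequal(split(Pm, row(Pm)), split(Qm, row(Qm)))
    }
  }
})

test_that("HD95 matches a brute-force pooled percentile and its bounds", {
  m <- rand_mask(c(6, 6, 4), 0.2)
  expect_equal(hd95(m, m, c(1, 1, 1)), 0)
  expect_true(is.na(hd95(m, array(FALSE, dim(m)), c(1, 1, 1))))

  set.seed(24)
  for (i in 1:6) {
    a <- rand_mask(c(6, 6, 4), 0.15)
    b <- rand_mask(c(6, 6, 4), 0.15)
    if (sum(a) == 0 || sum(b) == 0) next
    sp <- c(0.5, 0.5, 2)
    Pa <- sweep(which(mask_boundary(a), arr.ind = TRUE), 2, sp, `*`)
    Pb <- sweep(which(mask_boundary(b), arr.ind = TRUE), 2, sp, `*`)
    pooled <- c(naive_min_dists(Pa, Pb), naive_min_dists(Pb, Pa))
    expect_equal(hd95(a, b, sp),
                 unname(quantile(pooled, 0.95, type = 7)), tolerance = 1e-9)
    # the 95th percentile never exceeds the max-Hausdorff of the boundaries
    expect_lte(hd95(a, b, sp), hausdorff(which(mask_boundary(a), arr.ind = TRUE),
                                         which(mask_boundary(b), arr.ind = TRUE),
                                         sp) + 1e-12)
    # doubling the spacing doubles the distance exactly
    expect_equal(hd95(a, b, 2 * sp), 2 * hd95(a, b, sp), tolerance = 1e-12)
  }
})

test_that("boundary extraction marks exactly the face-exposed voxels", {
  m <- array(FALSE, c(5, 5, 5))
  m[2:4, 2:4, 2:4] <- TRUE
  b <- mask_boundary(m)
  expect_false(b[3, 3, 3])                 # interior voxel
  expect_true(all(b[2, 2:4, 2:4]))         # faces exposed
  expect_equal(sum(b), 26)                 # 3^3 minus the centre
  edge <- array(TRUE, c(3, 3, 3))          # mask touching the array edge
  expect_true(all(mask_boundary(edge)[1, , ]))
})

test_that("volume evaluation reports per-structure rows with the NA policy", {
  cs <- generate_case(phantom_spec(), seed = 31L)
  ev <- evaluate_volume(cs$mask, cs$mask, cs$spacing_mm, "self")
  expect_equal(ev$dsc[ev$structure == "GTVp"], 1)
  expect_equal(ev$dsc[ev$structure == "GTVn"], 1)
  expect_equal(ev$hd95_mm[ev$structure == "avg"], 0)

  # GTVp absent from both gt and pred: row undefined, excluded from the avg
  gt <- cs$mask; gt[gt == 1L] <- 0L
  pred <- gt
  ev2 <- evaluate_volume(gt, pred, cs$spacing_mm)
  expect_true(is.na(ev2$dsc[ev2$structure == "GTVp"]))
  expect_equal(ev2$dsc[ev2$structure == "avg"],
               ev2$dsc[ev2$structure == "GTVn"])

  bad <- cs$mask; bad[1] <- 3L
  expect_error(evaluate_volume(cs$mask, bad, cs$spacing_mm), "labels")

  # compositional: rows equal the metric ops called directly
  pred3 <- cs$mask
  pred3[, , 5] <- 0L
  ev3 <- evaluate_volume(cs$mask, pred3, cs$spacing_mm)
  expect_equal(ev3$dsc[1], dsc_pair(cs$mask == 1, pred3 == 1))
  expect_equal(ev3$hd95_mm[2], hd95(cs$mask == 2, pred3 == 2, cs$spacing_mm))
})

test_that("metric reports aggregate and serialise", {
  cases <- generate_cohort(3L, base_seed = 40L, spec = phantom_spec())
  gts <- lapply(cases, `[[`, "mask")
  preds <- gts
  preds[[2]][preds[[2]] == 1L] <- 0L       # drop GTVp from one prediction
  rep <- metric_report(gts, preds, list(c(0.5, 0.5, 2)), names(cases))
  expect_s3_class(rep$per_case, "data.frame")
  expect_equal(rep$aggregated$GTVn, 1)
  expect_lt(rep$aggregated$GTVp, 1)
  expect_equal(rep$averages$n_undefined_dsc, 0L)

  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_metric_report(rep, csv, js)
  expect_true(file.exists(csv) && file.exists(js))
  parsed <- jsonlite::read_json(js)
  expect_named(parsed, c("GTVp", "GTVn", "avg"))
})
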