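test_that("Dice coefficient matches explicit voxel counting", {
  a <- array(FALSE, c(4, 4, 4)); a[1:2, 1:2, 1:2] <- TRUE   # 8-voxel cube
  b <- array(FALSE, c(4, 4, 4)); b[1:2, 1:2, 1] <- TRUE     # half of it
  expect_equal(dice_coefficient(a, b), 2 * 4 / (8 + 4))
  expect_equal(dice_coefficient(a, a), 1)
  disj <- array(FALSE, c(4, 4, 4)); disj[4, 4, 4] <- TRUE
  expect_equal(dice_coefficient(a, disj), 0)
  expect_warning(d0 <- dice_coefficient(array(FALSE, c(2, 2, 2)),
                                        array(FALSE, c(2, 2, 2))), "empty")
  expect_equal(d0, 1)
  expect_error(dice_coefficient(a, array(FALSE, c(3, 3, 3))), "match")
})

test_that("Dice agrees with counting on random mask pairs and is symmetric", {
  set.seed(202)
  for (i in 1:100) {
    a <- array(runif(27) < 0.5, c(3, 3, 3))
    b <- array(runif(27) < 0.5, c(3, 3, 3))
    oracle <- if (sum(a) + sum(b) == 0) 1 else 2 * sum(a & b) / (sum(a) + sum(b))
    if (sum(a) + sum(b) == 0) {
      expect_warning(d <- dice_coefficient(a, b))
    } else d <- dice_coefficient(a, b)
    expect_identical(d, oracle)
    if (sum(a) + sum(b) > 0) expect_identical(dice_coefficient(b, a), d)
  }
})

test_that("exact Wilcoxon signed-rank matches the enumeration oracle", {
  # hand-checkable cases
  expect_warning(r <- wilcoxon_signed_rank(1:5, 1:5), "zero")
  expect_equal(r$p_value, 1)

  r6 <- wilcoxon_signed_rank(c(2, 4, 6, 8, 10, 12), c(1, 2, 3, 4, 5, 6))
  expect_equal(r6$p_value, 2 / 64)

  # five positive, one negative with the smallest absolute rank
  x <- c(10, 20, 30, 40, 50, 5.5); y <- c(5, 10, 15, 20, 25, 6)
  r5 <- wilcoxon_signed_rank(x, y)
  expect_equal(r5$p_value, 4 / 64)

  set.seed(303)
  for (i in 1:100) {
    n <- sample(2:10, 1)
    x <- round(rnorm(n), 1)
    y <- round(rnorm(n), 1)
    if (all(x == y)) next
    got <- suppressWarnings(wilcoxon_signed_rank(x, y))
    expect_equal(got$p_value, wilcoxon_enum_oracle(x, y), tolerance = 1e-12,
                 label = sprintf("seeded case %d", i))
  }
})

test_that("exact Wilcoxon agrees with stats::wilcox.test on tie-free data", {
  set.seed(404)
  for (i in 1:20) {
    n <- sample(c(6, 9, 12), 1)
    x <- rnorm(n); y <- rnorm(n)
    ours <- wilcoxon_signed_rank(x, y)
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-12)
  }
})

test_that("compartment_stats computes volumes, PDFF means and deltas", {
  g <- list(dim = c(20L, 20L, 20L), spacing = c(3.1, 2.0, 3.0),
            origin = c(0, 0, 0), orientation = diag(3))
  lab <- array(0L, g$dim)
  lab[2:11, 2:11, 2:11] <- 1L   # 1000 voxels of compartment 1
  for (cc in 2:6) lab[cc + 3, 15, 15] <- cc
  gt <- new_label_volume(lab, g$spacing, g$origin)
  pdff <- new_volume3d(array(6.66, g$dim), g$spacing, g$origin)
  st <- compartment_stats(gt, gt, pdff)
  expect_equal(st$dice, rep(1, 6))
  expect_equal(st$gt_volume_cm3[1], 1000 * 3.1 * 2.0 * 3.0 / 1000)
  expect_equal(st$gt_pdff[1], 6.66)
  expect_equal(st$delta_pdff, rep(0, 6))

  # AS dilated into a fattier rim: AS mean PDFF must exceed GT mean PDFF
  pd <- array(6.66, g$dim)
  pd[lab == 0L] <- 70
  lab_as <- lab
  lab_as[1:12, 1:12, 1:12][lab[1:12, 1:12, 1:12] == 0L] <- 1L
  as_ <- new_label_volume(lab_as, g$spacing, g$origin)
  st2 <- compartment_stats(gt, as_, new_volume3d(pd, g$spacing, g$origin))
  expect_gt(st2$as_pdff[1], st2$gt_pdff[1])

  # missing GT compartment flagged, not zeroed
  lab3 <- lab; lab3[lab3 == 6L] <- 0L
  expect_warning(st3 <- compartment_stats(new_label_volume(lab3, g$spacing, g$origin),
                                          gt, pdff), "missing")
  expect_true(is.na(st3$dice[6]))
})

test_that("cohort evaluation is the identity for AS = GT", {
  g <- list(dim = c(12L, 12L, 12L), spacing = c(2, 2, 2), origin = c(0, 0, 0))
  mk <- function(shift) {
    lab <- array(0L, c(12, 12, 12))
    for (cc in 1:6) lab[cc + shift, 2:5, 2:5] <- cc
    new_label_volume(lab, g$spacing, g$origin)
  }
  pdff <- new_volume3d(array(10, c(12, 12, 12)), g$spacing, g$origin)
  stats_list <- lapply(1:4, function(i) {
    lv <- mk(sample(1:3, 1))
    compartment_stats(lv, lv, pdff)
  })
  res <- suppressWarnings(evaluate_cohort(stats_list))
  expect_equal(res$dice, rep(1, 7))
  expect_equal(res$delta_pdff, rep(0, 7))
  expect_equal(res$p_pdff, rep(1, 7))
  expect_equal(res$p_volume, rep(1, 7))
})
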