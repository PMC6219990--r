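test_that("NIfTI write/read round-trips data and geometry", {
  # float32-representable values (multiples of 1/2) so the round-trip is
  # bit exact
  arr <- array(seq(0.5, 32, by = 0.5), dim = c(4, 4, 4))
  v <- new_volume3d(arr, spacing = c(3.1, 2.0, 3.0), origin = c(-10, 5, 2))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  r <- read_volume(f)
  expect_equal(r$data, v$data, tolerance = 0)
  expect_equal(r$spacing, v$spacing, tolerance = 1e-5)
  expect_equal(r$origin, v$origin, tolerance = 1e-4)
  expect_equal(r$orientation, v$orientation, tolerance = 1e-6)

  lab <- new_label_volume(array(rep(0:3, 16), c(4, 4, 4)), c(1, 1, 1))
  fl <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(lab, fl)
  rl <- read_volume(fl, labels = TRUE)
  expect_identical(rl$data, lab$data)
  expect_s3_class(rl, "label_volume")
})

test_that("read_volume rejects 2-D images and bad labels", {
  f <- withr::local_tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(matrix(1, 4, 4)), f)
  expect_error(read_volume(f), "3-D")

  bad <- new_volume3d(array(7, c(2, 2, 2)), c(1, 1, 1))
  fb <- withr::local_tempfile(fileext = ".nii")
  write_volume(bad, fb)
  expect_error(read_volume(fb, labels = TRUE), "7")
})

test_that("volume constructors enforce geometry invariants", {
  expect_error(new_volume3d(array(0, c(2, 2)), c(1, 1, 1)), "3-D")
  expect_error(new_volume3d(array(0, c(2, 2, 2)), c(1, -1, 1)), "positive")
  skewed <- matrix(c(1, 0.1, 0, 0, 1, 0, 0, 0, 1), 3, 3)
  expect_error(new_volume3d(array(0, c(2, 2, 2)), c(1, 1, 1),
                            orientation = skewed), "orthonormal")
  expect_error(new_label_volume(array(9L, c(2, 2, 2)), c(1, 1, 1)), "0..6")
})

test_that("world/index mapping round-trips", {
  th <- 0.3
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  v <- new_volume3d(array(0, c(5, 6, 7)), c(1.5, 2, 2.5), origin = c(3, -4, 9),
                    orientation = rot)
  idx <- as.matrix(expand.grid(0:4, 0:5, 0:6))
  back <- world_to_index(v, index_to_world(v, idx))
  expect_lt(max(abs(back - idx)), 1e-9)
})

test_that("PDFF map follows fat / (fat + water), with signal-void handling", {
  g <- c(6L, 6L, 6L)
  w <- new_volume3d(array(1, g), c(1, 1, 1))
  f0 <- new_volume3d(array(0, g), c(1, 1, 1))
  expect_equal(max(abs(compute_pdff_map(w, f0)$data)), 0)

  half <- new_volume3d(array(0.5, g), c(1, 1, 1))
  expect_equal(compute_pdff_map(half, half)$data, array(50, g))

  # one signal-void voxel goes to 0 and is counted
  wa <- array(1, g); fa <- array(1, g)
  wa[1, 1, 1] <- 0; fa[1, 1, 1] <- 0
  expect_warning(
    p <- compute_pdff_map(new_volume3d(wa, c(1, 1, 1)),
                          new_volume3d(fa, c(1, 1, 1))),
    "signal-void")
  expect_equal(p$data[1, 1, 1], 0)
  expect_equal(attr(p, "signal_void"), 1L)

  expect_error(compute_pdff_map(w, new_volume3d(array(0, c(2, 2, 2)), c(1, 1, 1))),
               "geometry")
  expect_error(compute_pdff_map(w, new_volume3d(array(-1, g), c(1, 1, 1))),
               "negative")
})

test_that("PDFF is scale invariant and bounded", {
  set.seed(11)
  g <- c(8L, 8L, 8L)
  w <- new_volume3d(array(runif(prod(g)), g), c(1, 1, 1))
  f <- new_volume3d(array(runif(prod(g)), g), c(1, 1, 1))
  p1 <- compute_pdff_map(w, f)
  for (cc in c(0.001, 3.7, 1e5)) {
    w2 <- w; w2$data <- w$data * cc
    f2 <- f; f2$data <- f$data * cc
    p2 <- compute_pdff_map(w2, f2)
    expect_lt(max(abs(p2$data - p1$data)), 1e-9)
  }
  expect_gte(min(p1$data), 0)
  expect_lte(max(p1$data), 100)
})

test_that("resampling: identity, constants and linear ramps are exact", {
  g <- c(8L, 6L, 5L)
  ramp <- array(rep(0:(g[1] - 1), prod(g[2:3])), g)  # linear in x index
  v <- new_volume3d(ramp, c(2, 2, 2), origin = c(0, 0, 0))

  same <- resample_to_grid(v, vol_geometry(v), "linear")
  expect_equal(same$data, v$data, tolerance = 1e-12)

  const <- new_volume3d(array(4.2, g), c(2, 2, 2))
  tg <- list(dim = c(5L, 5L, 4L), spacing = c(1.7, 2.0, 1.9),
             origin = c(1, 1, 1), orientation = diag(3))
  expect_equal(unique(as.vector(resample_to_grid(const, tg, "linear")$data)), 4.2)

  # half spacing along x: interior new samples sit at neighbor midpoints
  tg2 <- list(dim = c(15L, 6L, 5L), spacing = c(1, 2, 2), origin = c(0, 0, 0),
              orientation = diag(3))
  r <- resample_to_grid(v, tg2, "linear")
  expect_equal(r$data[2, 1, 1], (ramp[1, 1, 1] + ramp[2, 1, 1]) / 2 * 1)
  expect_equal(r$data[3, 1, 1], ramp[2, 1, 1])
  expect_equal(r$data[8, 3, 2], 3.5)

  lab <- new_label_volume(array(1L, g), c(2, 2, 2))
  expect_error(resample_to_grid(lab, tg, "linear"), "nearest")
  expect_identical(unique(as.vector(resample_to_grid(lab, tg, "nearest")$data)), 1L)
})
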