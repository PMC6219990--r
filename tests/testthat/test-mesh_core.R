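test_that("mesh_volume matches analytic values and enforces orientation", {
  cube <- cube_mesh(lo = 0, edge = 10)
  expect_true(mesh_is_closed(cube))
  expect_equal(mesh_volume(cube), 1.0, tolerance = 1e-12)

  sph <- uv_sphere(radius = 10, nu = 64, nv = 32)
  expect_true(mesh_is_closed(sph))
  expect_lt(abs(mesh_volume(sph) - 4.18879) / 4.18879, 0.01)

  rev <- sph
  rev$triangles <- rev$triangles[, c(1, 3, 2)]
  expect_error(mesh_volume(rev), "orientation")

  open <- cube
  open$triangles <- open$triangles[-1, ]
  expect_error(mesh_volume(open), "closed")
})

test_that("voxelization counts voxels of analytic solids correctly", {
  # cube [0,10]^3 on a unit grid with centers at 0.5..9.5: exactly 1000
  grid <- list(dim = c(12L, 12L, 12L), spacing = c(1, 1, 1),
               origin = c(-0.5, -0.5, -0.5), orientation = diag(3))
  lab <- voxelize(cube_mesh(0, 10), grid)
  expect_equal(sum(lab$data == 1L), 1000L)

  # mesh entirely outside the grid -> all background
  far <- voxelize(cube_mesh(100, 10), grid)
  expect_equal(sum(far$data), 0L)

  # sphere radius 8 mm on a 1 mm grid: within 2% of the analytic volume
  sgrid <- list(dim = c(24L, 24L, 24L), spacing = c(1, 1, 1),
                origin = c(-11.5, -11.5, -11.5), orientation = diag(3))
  sl <- voxelize(uv_sphere(radius = 8, nu = 64, nv = 32), sgrid)
  expect_lt(abs(sum(sl$data) - 4 / 3 * pi * 8^3) / (4 / 3 * pi * 8^3), 0.02)
})

test_that("compartment extraction approximates the mask iso-surface", {
  # single labeled voxel: closed mesh, volume positive and at most one voxel
  g <- c(9L, 9L, 9L)
  one <- array(0L, g); one[5, 5, 5] <- 1L
  lv <- new_label_volume(one, c(1, 1, 1))
  m1 <- extract_compartment_mesh(lv, 1)
  expect_true(mesh_is_closed(m1))
  v1 <- mesh_volume(m1)
  expect_gt(v1, 0)
  expect_lte(v1, 1e-3)

  # digitized sphere radius 8: mesh volume within 5% of analytic (both methods)
  sl <- sphere_label_volume(radius = 8, dim = c(24L, 24L, 24L))
  for (method in c("wrap", "marching")) {
    ms <- extract_compartment_mesh(sl, 1, method = method)
    expect_true(mesh_is_closed(ms))
    expect_lt(abs(mesh_volume(ms) * 1000 - 4 / 3 * pi * 8^3) / (4 / 3 * pi * 8^3),
              0.05)
  }
  expect_error(extract_compartment_mesh(sl, 3), "absent")
})

test_that("voxelize/extract round-trip keeps Dice >= 0.95 on smooth blobs", {
  # blob: union-ish smooth shape from a deformed sphere SDF
  d <- c(30L, 30L, 30L)
  idx <- as.matrix(expand.grid(0:29, 0:29, 0:29)) - 14.5
  r <- sqrt(rowSums(idx^2))
  bump <- 2.5 * sin(idx[, 1] / 4) * cos(idx[, 2] / 5)
  mask <- array(as.integer(r - (9 + bump) < 0), d)
  lv <- new_label_volume(mask, c(1, 1, 1))
  for (method in c("wrap", "marching")) {
    mesh <- extract_compartment_mesh(lv, 1, method = method)
    back <- voxelize(mesh, vol_geometry(lv))
    expect_gte(dice_coefficient(back$data == 1, mask == 1), 0.95)
    # voxel count x voxel volume agrees with the mesh volume within 3%
    vox_vol <- sum(back$data == 1) / 1000
    expect_lt(abs(vox_vol - mesh_volume(mesh)) / mesh_volume(mesh), 0.03)
  }
})

test_that("smoothing preserves closure and volume", {
  sl <- sphere_label_volume(radius = 8, dim = c(24L, 24L, 24L))
  m <- extract_compartment_mesh(sl, 1, method = "marching", smoothing = 0)
  v0 <- mesh_volume(m)
  sm <- smooth_mesh(m, 10)
  expect_true(mesh_is_closed(sm))
  expect_lt(abs(mesh_volume(sm) - v0) / v0, 0.02)
})

test_that("shrink_mesh moves the surface inward by the requested distance", {
  sph <- uv_sphere(radius = 10, nu = 48, nv = 24)
  expect_identical(shrink_mesh(sph, 0), sph)

  s1 <- shrink_mesh(sph, 1)
  expect_true(mesh_is_closed(s1))
  target <- 4 / 3 * pi * 9^3 / 1000
  expect_lt(abs(mesh_volume(s1) - target) / target, 0.02)
  expect_lt(mesh_volume(s1), mesh_volume(sph))

  expect_error(shrink_mesh(sph, -1), "nonnegative")
  expect_error(shrink_mesh(sph, 11), "invert")
})

test_that("PLY round-trips plain and multi-compartment meshes", {
  tpl <- make_template()
  f <- withr::local_tempfile(fileext = ".ply")
  write_ply(tpl, f)
  back <- read_ply(f)
  expect_s3_class(back, "mc_mesh")
  expect_equal(back$triangle_labels, tpl$triangle_labels)
  expect_equal(back$vertices, tpl$vertices, tolerance = 1e-5)
  expect_equal(back$triangles, tpl$triangles)

  sph <- uv_sphere(nu = 12, nv = 6)
  f2 <- withr::local_tempfile(fileext = ".ply")
  write_ply(sph, f2)
  b2 <- read_ply(f2)
  expect_equal(b2$triangles, sph$triangles)
})
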