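# volumes with a planar step edge at a known world-x position
step_volume <- function(edge_x = 10.5, low = 5, high = 70,
                        dim = c(24L, 24L, 24L), spacing = c(1, 1, 1)) {
  idx <- as.matrix(expand.grid(0:(dim[1] - 1), 0:(dim[2] - 1), 0:(dim[3] - 1)))
  vals <- ifelse(idx[, 1] * spacing[1] < edge_x, low, high)
  new_volume3d(array(vals, dim), spacing)
}

test_that("profile sampling follows the image along the normal", {
  const <- new_volume3d(array(7.5, c(10, 10, 10)), c(1, 1, 1))
  p <- sample_profile(const, center = c(4.5, 4.5, 4.5), normal = c(1, 0, 0),
                      L = 3, step = 1)
  expect_equal(nrow(p), 7)
  expect_equal(p$intensity, rep(7.5, 7))
  expect_equal(p$offset, -3:3)

  # linear ramp: intensity linear in offset with the ramp slope
  ramp <- new_volume3d(array(rep(0:9 * 2.5, 100), c(10, 10, 10)), c(1, 1, 1))
  pr <- sample_profile(ramp, c(4.5, 5, 5), c(1, 0, 0), L = 3, step = 0.5)
  fit <- stats::lm(intensity ~ offset, data = pr)
  expect_equal(unname(coef(fit)[2]), 2.5, tolerance = 1e-9)
  expect_lt(max(abs(residuals(fit))), 1e-9)

  # center far outside: every sample flagged
  po <- sample_profile(const, c(100, 100, 100), c(1, 0, 0), L = 3, step = 1)
  expect_true(all(!po$inside))
  expect_true(all(is.na(po$intensity)))

  expect_error(sample_profile(const, c(5, 5, 5), c(0, 0, 0), 3, 1), "normal")
  expect_error(sample_profile(const, c(5, 5, 5), c(1, 0, 0), 0.5, 1), "step")
})

test_that("feature response gates polarity, window and damping", {
  vol <- step_volume(edge_x = 10, low = 0, high = 8)
  # rendered edge midpoint sits between voxel centers 9 and 10, i.e. at
  # x = 9.5: offset +1 from a profile centered at x = 8.5
  p <- sample_profiles(vol, matrix(c(8.5, 12, 12), 1), matrix(c(1, 0, 0), 1),
                       L = 6, step = 1)
  rising <- list(polarity = "rising", window = c(-Inf, Inf), damping = 100)
  r <- feature_response(p, rising)
  k <- which.max(r[1, ])
  expect_equal(p$offsets[k], 1)

  falling <- list(polarity = "falling", window = c(-Inf, Inf), damping = 100)
  expect_equal(max(feature_response(p, falling)), 0)

  capped <- list(polarity = "rising", window = c(-Inf, Inf), damping = 0.4)
  expect_equal(max(feature_response(p, capped)), 0.4)

  # window excluding the mid-edge intensity zeroes the response there
  gated <- list(polarity = "rising", window = c(20, 30), damping = 100)
  expect_equal(max(feature_response(p, gated)), 0)
})

test_that("feature training prefers the informative channel", {
  # idealized cohort: six well-separated spheres, fat channel a clean step
  # at every boundary, water channel featureless noise
  centers <- rbind(c(-30, 25, 0), c(30, 25, 0), c(-30, -25, 0),
                   c(30, -25, 0), c(-30, 0, 28), c(30, 0, 28))
  mesh <- new_mc_mesh(lapply(1:6, function(i)
    uv_sphere(radius = 14, center = centers[i, ], nu = 16, nv = 8)))
  grid <- list(dim = c(46L, 40L, 32L), spacing = c(2.2, 2.2, 2.2),
               origin = c(-49, -42, -17), orientation = diag(3))
  labels <- voxelize(mesh, grid)
  fat_arr <- array(10, grid$dim)
  fat_arr[labels$data > 0] <- 80
  fat <- new_volume3d(fat_arr, grid$spacing, grid$origin)
  noise_vol <- function(seed) {
    set.seed(seed)
    new_volume3d(array(runif(prod(grid$dim), 40, 60), grid$dim),
                 grid$spacing, grid$origin)
  }
  model <- list(mean_mesh = mesh)
  class(model) <- "shape_model"
  subs <- list(list(water = noise_vol(1), fat = fat, mesh = mesh),
               list(water = noise_vol(2), fat = fat, mesh = mesh))
  fm <- train_features(model, subs, L = 8, step = 1)
  expect_gte(mean(fm$weight_water < 0.1), 0.9)
  # clean cohort: residual of the informative channel within one step
  expect_lt(mean(fm$residual_fat), 1)

  # identical channels: weights 0.5 by the tie rule
  subs_eq <- list(list(water = fat, fat = fat, mesh = mesh),
                  list(water = fat, fat = fat, mesh = mesh))
  fm_eq <- train_features(model, subs_eq, L = 8, step = 2)
  expect_equal(fm_eq$weight_water, rep(0.5, fm_eq$n_triangles))

  expect_error(train_features(model, subs[1], L = 8, step = 2), "2 subjects")
})

test_that("enlarging the candidate catalogue never worsens the best residual", {
  spec <- small_phantom_spec(noise_sd = 0.02)
  subj <- sample_subject(spec, 6)
  g <- paraseg:::triangle_geometry(subj$mesh)
  prof <- sample_profiles(subj$fat, g$centroids, g$normals, L = 8, step = 2)
  cat_full <- default_feature_catalogue(as.numeric(subj$fat$data))
  residual_for <- function(cat) {
    res <- sapply(seq_len(nrow(cat)), function(ci) {
      cand <- paraseg:::catalogue_candidate(cat, ci)
      resp <- feature_response(prof, cand)
      pk <- paraseg:::pick_peaks(resp, prof$offsets, gamma = 0, refine = FALSE)
      ifelse(pk$response <= 0, 8, abs(pk$offset))
    })
    apply(matrix(res, ncol = nrow(cat)), 1, min)
  }
  r_small <- residual_for(cat_full[1:6, ])
  r_full <- residual_for(cat_full)
  expect_true(all(r_full <= r_small + 1e-12))
})

test_that("target detection finds edges where they are", {
  spec <- small_phantom_spec(noise_sd = 0)
  subj <- sample_subject(spec, 9)
  mesh <- subj$mesh
  model <- list(mean_mesh = mesh); class(model) <- "shape_model"
  subs <- list(list(water = subj$water, fat = subj$fat, mesh = mesh),
               list(water = subj$water, fat = subj$fat, mesh = mesh))
  fm <- train_features(model, subs, L = 8, step = 1)

  # image edges lie on the mesh: offsets concentrate at zero, weights positive
  tg0 <- detect_target_points(mesh, subj$water, subj$fat, fm)
  expect_gt(mean(tg0$weights > 0), 0.95)
  expect_lt(mean(abs(tg0$offsets[tg0$weights > 0])), 1)

  # mesh displaced 3 mm inward along normals: detected offsets ~ +3 mm
  g <- paraseg:::triangle_geometry(mesh)
  vn <- vertex_normals(mesh)
  inner <- set_vertices(mesh, mesh$vertices - 3 * vn)
  tgi <- detect_target_points(inner, subj$water, subj$fat, fm)
  ok <- tgi$weights > 0
  expect_gt(median(tgi$offsets[ok]), 1.5)

  # featureless image: all weights zero
  flat <- new_volume3d(array(50, vol_dim(subj$fat)), subj$fat$spacing,
                       subj$fat$origin)
  tgf <- detect_target_points(mesh, flat, flat, fm)
  expect_equal(max(tgf$weights), 0)
})

test_that("detection is translation equivariant", {
  spec <- small_phantom_spec(noise_sd = 0)
  subj <- sample_subject(spec, 12)
  mesh <- subj$mesh
  model <- list(mean_mesh = mesh); class(model) <- "shape_model"
  subs <- list(list(water = subj$water, fat = subj$fat, mesh = mesh),
               list(water = subj$water, fat = subj$fat, mesh = mesh))
  fm <- train_features(model, subs, L = 8, step = 2)
  tg0 <- detect_target_points(mesh, subj$water, subj$fat, fm)

  shift <- c(6.2, -4, 6)  # whole voxels: image content is exactly preserved
  wat2 <- subj$water; wat2$origin <- wat2$origin + shift
  fat2 <- subj$fat; fat2$origin <- fat2$origin + shift
  mesh2 <- set_vertices(mesh, sweep(mesh$vertices, 2, shift, "+"))
  tg2 <- detect_target_points(mesh2, wat2, fat2, fm)
  ok <- tg0$weights > 0 & tg2$weights > 0
  expect_gt(mean(ok), 0.9)
  expect_lt(max(abs(tg2$offsets[ok] - tg0$offsets[ok])), 0.1)
})
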