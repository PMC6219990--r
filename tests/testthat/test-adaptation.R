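test_that("point-to-plane rigid solve recovers known transforms", {
  sph <- uv_sphere(radius = 20, nu = 24, nv = 12)
  g <- paraseg:::triangle_geometry(sph)
  w <- rep(1, nrow(g$centroids))

  tf0 <- solve_global_transform(g$centroids, g$normals, g$centroids, w)
  expect_lt(max(abs(tf0$R - diag(3))), 1e-9)
  expect_lt(max(abs(tf0$t)), 1e-9)

  shift <- c(5, -3, 2)
  tf1 <- solve_global_transform(g$centroids, g$normals,
                                sweep(g$centroids, 2, shift, "+"), w)
  expect_lt(max(abs(tf1$t - shift)), 0.01)

  th <- 5 * pi / 180
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  cen <- paraseg:::mesh_centroid(sph)
  tgt <- sweep(sweep(g$centroids, 2, cen) %*% t(rot), 2, cen, "+")
  tf2 <- solve_global_transform(g$centroids, g$normals, tgt, w)
  ang <- paraseg:::rotation_angle(t(rot) %*% tf2$R) * 180 / pi
  expect_lt(ang, 0.1)

  expect_error(solve_global_transform(g$centroids[1:2, ], g$normals[1:2, ],
                                      g$centroids[1:2, ], w[1:2]),
               "degenerate")
})

test_that("free-form step honors its limiting regimes", {
  sph <- uv_sphere(radius = 15, nu = 16, nv = 8)
  g <- paraseg:::triangle_geometry(sph)
  nt <- nrow(g$centroids)
  ref <- sph$vertices
  set.seed(5)
  targets <- list(points = g$centroids + matrix(rnorm(nt * 3, 0, 2), nt, 3),
                  weights = runif(nt, 0.5, 1), normals = g$normals)

  # huge alpha: output pinned to the reference
  v_stiff <- free_form_step(sph, targets, ref, alpha = 1e9)
  expect_lt(max(abs(v_stiff - ref)), 0.01)

  # zero-weight targets: exactly the reference for any alpha > 0
  t0 <- targets; t0$weights <- rep(0, nt)
  v_ref <- free_form_step(sph, t0, ref, alpha = 0.7)
  expect_lt(max(abs(v_ref - ref)), 1e-8)

  expect_error(free_form_step(sph, t0, ref, alpha = 0), "singular")
})

test_that("free-form step matches a dense least-squares oracle on tiny meshes", {
  # tetrahedron-like small closed mesh: an octahedron (6 vertices)
  verts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1)) * 10
  tris <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
                c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  mesh <- new_triangle_mesh(verts, tris)
  expect_true(mesh_is_closed(mesh))
  g <- paraseg:::triangle_geometry(mesh)
  nt <- nrow(tris); nv <- nrow(verts)
  set.seed(8)
  for (case in 1:5) {
    targets <- list(points = g$centroids + matrix(rnorm(nt * 3), nt, 3),
                    weights = runif(nt), normals = g$normals)
    ref <- verts + matrix(rnorm(nv * 3, 0, 0.5), nv, 3)
    alpha <- runif(1, 0.1, 2)
    got <- free_form_step(mesh, targets, ref, alpha)

    # dense oracle built row by row
    A <- NULL; b <- NULL
    for (i in seq_len(nt)) {
      row <- numeric(3 * nv)
      for (c in 1:3) for (d in 1:3)
        row[(d - 1) * nv + tris[i, c]] <- g$normals[i, d] / 3
      A <- rbind(A, sqrt(targets$weights[i]) * row)
      b <- c(b, sqrt(targets$weights[i]) * sum(g$normals[i, ] * targets$points[i, ]))
    }
    e <- paraseg:::mesh_edges(mesh)
    for (k in seq_len(nrow(e))) for (d in 1:3) {
      row <- numeric(3 * nv)
      row[(d - 1) * nv + e[k, 1]] <- sqrt(alpha)
      row[(d - 1) * nv + e[k, 2]] <- -sqrt(alpha)
      A <- rbind(A, row)
      b <- c(b, sqrt(alpha) * (ref[e[k, 1], d] - ref[e[k, 2], d]))
    }
    for (j in seq_len(nv)) for (d in 1:3) {   # null-space tether
      row <- numeric(3 * nv)
      row[(d - 1) * nv + j] <- sqrt(alpha * 1e-6)
      A <- rbind(A, row)
      b <- c(b, sqrt(alpha * 1e-6) * ref[j, d])
    }
    oracle <- matrix(qr.solve(crossprod(A), crossprod(A, b)), nv, 3)
    expect_lt(max(abs(got - oracle)), 1e-6)
  }

  # alpha = 0 with full-weight targets on the planes through shifted
  # centroids: external energy vanishes at the optimum
  targets <- list(points = g$centroids + 0.5 * g$normals,
                  weights = rep(1, nt), normals = g$normals)
  v0 <- free_form_step(mesh, targets, verts, alpha = 0)
  cen <- (v0[tris[, 1], ] + v0[tris[, 2], ] + v0[tris[, 3], ]) / 3
  e_ext <- sum(rowSums(g$normals * (cen - targets$points))^2)
  expect_lt(e_ext, 1e-10)
})

test_that("joint rigid stage recovers known poses of a rendered phantom", {
  spec <- small_phantom_spec(noise_sd = 0.02, deform_amplitude = 0,
                             max_rot_deg = 0, max_trans_mm = 0)
  base <- sample_subject(spec, 50)
  tm <- small_trained_model()
  mean_mesh <- tm$shape_model$mean_mesh
  set.seed(60)
  for (i in 1:3) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    ang <- runif(1, 2, 10) * pi / 180
    tr <- runif(3, -1, 1); tr <- tr / sqrt(sum(tr^2)) * runif(1, 5, 15)
    pose <- list(R = paraseg:::rotation_from_axis_angle(ax * ang), t = tr)
    # phantom rendered from the mean mesh itself under the known transform
    posed <- set_vertices(mean_mesh, apply_rigid(pose, mean_mesh$vertices))
    labs <- paraseg:::voxelize_quiet(posed, paraseg:::phantom_grid(spec))
    ch <- paraseg:::render_channels(labs, base$pdff, spec, noise_seed = 1000 + i)
    tf <- recover_joint_rigid(tm, ch$water, ch$fat)
    ang_err <- paraseg:::rotation_angle(t(pose$R) %*% tf$R) * 180 / pi
    cen_true <- paraseg:::mesh_centroid(posed)
    cen_got <- paraseg:::mesh_centroid(
      set_vertices(mean_mesh, apply_rigid(tf, mean_mesh$vertices)))
    expect_lt(ang_err, 2)
    expect_lt(sqrt(sum((cen_got - cen_true)^2)), 1)
  }
})

test_that("free-form energy is non-increasing within each solve", {
  spec <- small_phantom_spec(noise_sd = 0.02)
  subs <- lapply(61:62, function(s) {
    x <- sample_subject(spec, s)
    list(water = x$water, fat = x$fat, labels = x$labels)
  })
  tm <- train_model(subs)
  test_subj <- sample_subject(spec, 63)
  res <- adapt(tm, test_subj$water, test_subj$fat)
  for (tr in res$energy) {
    if (is.null(tr)) next
    expect_true(all(tr[, "after"] <= tr[, "before"] * (1 + 1e-6) + 1e-6))
  }
  # rigid + free-form pipeline is exactly reproducible
  res2 <- adapt(tm, test_subj$water, test_subj$fat)
  expect_identical(res$mesh$vertices, res2$mesh$vertices)
})

test_that("adapt validates image geometry before computing", {
  spec <- small_phantom_spec()
  subs <- lapply(71:72, function(s) {
    x <- sample_subject(spec, s)
    list(water = x$water, fat = x$fat, labels = x$labels)
  })
  tm <- train_model(subs)
  subj <- sample_subject(spec, 73)
  wrong <- subj$fat
  wrong$origin <- wrong$origin + 5
  expect_error(adapt(tm, subj$water, wrong), "geometry")
})

test_that("adaptation improves on the initialization for deformed phantoms", {
  spec <- small_phantom_spec(noise_sd = 0.02)
  subs <- lapply(81:84, function(s) {
    x <- sample_subject(spec, s)
    list(water = x$water, fat = x$fat, labels = x$labels)
  })
  tm <- train_model(subs)
  subj <- sample_subject(spec, 99)
  res <- adapt(tm, subj$water, subj$fat)
  lab <- suppressWarnings(voxelize(res$mesh, vol_geometry(subj$labels)))

  # initialization: mean mesh translated to the GHT estimate
  loc <- locate(subj$water, subj$fat, tm$ght_model)
  init <- set_vertices(tm$shape_model$mean_mesh,
                       sweep(tm$shape_model$mean_mesh$vertices, 2,
                             loc$translation, "+"))
  lab0 <- suppressWarnings(voxelize(init, vol_geometry(subj$labels)))
  for (cc in 1:6) {
    d_init <- dice_coefficient(lab0$data == cc, subj$labels$data == cc)
    d_final <- dice_coefficient(lab$data == cc, subj$labels$data == cc)
    expect_gte(d_final, d_init)
  }
  expect_gt(mean(sapply(1:6, function(cc)
    dice_coefficient(lab$data == cc, subj$labels$data == cc))), 0.9)
})
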