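# The end-to-end phantom benchmark takes a few minutes; several acceptance
# checks share one run through this cache.
.benchmark_cache <- new.env(parent = emptyenv())

default_benchmark <- function() {
  if (is.null(.benchmark_cache$result))
    .benchmark_cache$result <- run_phantom_study(seed = 42)
  .benchmark_cache$result
}

# small trained model on the half-resolution phantom, shared across tests
small_trained_model <- function() {
  if (is.null(.benchmark_cache$small_model)) {
    spec <- small_phantom_spec(noise_sd = 0.02, max_rot_deg = 0,
                               max_trans_mm = 0)
    subs <- lapply(951:952, function(s) {
      x <- sample_subject(spec, s)
      list(water = x$water, fat = x$fat, labels = x$labels)
    })
    .benchmark_cache$small_model <- train_model(subs)
  }
  .benchmark_cache$small_model
}

# the pipeline's rigid stage in isolation: GHT initialization followed by
# joint point-to-plane rigid iterations over all six compartments, coarse
# then fine
recover_joint_rigid <- function(model, water, fat) {
  loc <- locate(water, fat, model$ght_model, step = 6)
  mean_mesh <- model$shape_model$mean_mesh
  fm <- model$feature_model
  tf <- list(R = diag(3), t = loc$translation)
  for (pass in list(list(scale = 2, L = 20, step = 2),
                    list(scale = 1, L = 10, step = 1))) {
    w <- downsample_volume(water, pass$scale)
    f <- downsample_volume(fat, pass$scale)
    mesh <- set_vertices(mean_mesh, apply_rigid(tf, mean_mesh$vertices))
    for (it in 1:20) {
      tg <- detect_target_points(mesh, w, f, fm, L = pass$L, step = pass$step)
      if (sum(tg$weights > 0) < 3) break
      g <- paraseg:::triangle_geometry(mesh)
      upd <- solve_global_transform(g$centroids, g$normals, tg$points,
                                    tg$weights)
      tf <- paraseg:::compose_rigid(upd, tf)
      newV <- apply_rigid(tf, mean_mesh$vertices)
      mv <- mean(sqrt(rowSums((newV - mesh$vertices)^2)))
      mesh <- set_vertices(mesh, newV)
      if (mv < 0.02) break
    }
  }
  tf
}
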