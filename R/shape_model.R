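# Mean-shape construction: rigid pose normalization of training label
# volumes, fuzzy (signed-distance) shape averaging, and training-time
# correspondence by adapting the mean mesh back to each subject's labels.

label_centroids <- function(labels) {
  d <- vol_dim(labels)
  out <- matrix(NA_real_, 6, 3)
  idx_all <- which(labels$data != 0)
  if (!length(idx_all)) stop("label volume is empty")
  ai <- arrayInd(idx_all, d) - 1
  lv <- labels$data[idx_all]
  for (cc in 1:6) {
    sel <- lv == cc
    if (!any(sel)) stop("compartment ", cc, " missing from label volume")
    out[cc, ] <- colMeans(index_to_world(labels, ai[sel, , drop = FALSE]))
  }
  out
}

#' Rigidly align a training set of label volumes
#'
#' Each subject is aligned to the first by a least-squares rigid transform on
#' the six compartment centroids (no scaling), then resampled (nearest
#' neighbor) onto the reference grid.
#'
#' @param labelsets list of `label_volume`s, each containing all six
#'   compartments.
#' @return list with `aligned` (label volumes on the reference grid) and
#'   `transforms` (per subject, mapping subject coordinates to the reference
#'   frame).
#' @export
align_training_set <- function(labelsets) {
  if (!length(labelsets)) stop("empty training set")
  cen <- lapply(labelsets, label_centroids)
  ref <- labelsets[[1]]
  out <- vector("list", length(labelsets))
  tfs <- vector("list", length(labelsets))
  for (s in seq_along(labelsets)) {
    tf <- if (s == 1) rigid_identity() else kabsch_rigid(cen[[s]], cen[[1]])
    tfs[[s]] <- tf
    if (s == 1) {
      out[[s]] <- ref
    } else {
      # resample subject labels into the reference frame: target voxel x maps
      # back through tf^-1 into the subject volume
      inv <- invert_rigid(tf)
      geo <- vol_geometry(ref)
      d <- geo$dim
      idx <- as.matrix(expand.grid(0:(d[1] - 1), 0:(d[2] - 1), 0:(d[3] - 1)))
      world_ref <- index_to_world(geo, idx)
      src_idx <- round(world_to_index(labelsets[[s]], apply_rigid(inv, world_ref)))
      sd <- vol_dim(labelsets[[s]])
      ok <- src_idx[, 1] >= 0 & src_idx[, 1] <= sd[1] - 1 &
        src_idx[, 2] >= 0 & src_idx[, 2] <= sd[2] - 1 &
        src_idx[, 3] >= 0 & src_idx[, 3] <= sd[3] - 1
      vals <- integer(nrow(src_idx))
      lin <- src_idx[ok, 1] + sd[1] * (src_idx[ok, 2] + sd[2] * src_idx[ok, 3])
      vals[ok] <- as.integer(labelsets[[s]]$data)[lin + 1]
      out[[s]] <- new_label_volume(array(vals, d), geo$spacing, geo$origin,
                                   geo$orientation)
    }
  }
  list(aligned = out, transforms = tfs)
}

common_average_grid <- function(labelsets, pad_vox = 5) {
  # bounding box of all nonzero voxels over all (aligned) subjects, padded,
  # at the finest spacing present
  sp <- do.call(rbind, lapply(labelsets, function(l) l$spacing))
  spacing <- apply(sp, 2, min)
  lo <- rep(Inf, 3); hi <- rep(-Inf, 3)
  for (l in labelsets) {
    idx <- which(l$data != 0)
    ai <- arrayInd(idx, vol_dim(l)) - 1
    w <- index_to_world(l, ai)
    lo <- pmin(lo, apply(w, 2, min))
    hi <- pmax(hi, apply(w, 2, max))
  }
  lo <- lo - pad_vox * spacing
  hi <- hi + pad_vox * spacing
  d <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  list(dim = d, spacing = spacing, origin = lo, orientation = diag(3))
}

#' Fuzzy shape averaging of one compartment across subjects
#'
#' Converts each subject's binary compartment mask to a truncated signed
#' distance field, averages the fields on a common grid, and extracts the
#' zero iso-surface of the mean field: the fuzzy-average surface.
#'
#' @param labelsets list of pose-aligned `label_volume`s.
#' @param compartment label 1-6.
#' @param grid optional common grid (default: padded bounding box of all
#'   masks at the finest input spacing).
#' @param trunc_vox signed-distance truncation in voxels of the finest
#'   spacing (fuzzy membership saturation).
#' @param method surface extraction: `"wrap"` (shrink-wrapped tube with a
#'   fixed triangle budget, default) or `"marching"` (marching tetrahedra).
#' @param mesh_spacing iso-surface grid spacing (mm) for `"marching"`.
#' @param smoothing Laplacian smoothing iterations (`"marching"` only).
#' @param n_theta,n_rings mesh resolution for `"wrap"`.
#' @return `triangle_mesh` of the average shape.
#' @export
fuzzy_average_labels <- function(labelsets, compartment, grid = NULL,
                                 trunc_vox = 10,
                                 method = c("wrap", "marching"),
                                 mesh_spacing = NULL, smoothing = 3,
                                 n_theta = 22, n_rings = 23) {
  method <- match.arg(method)
  if (!length(labelsets)) stop("empty training set")
  for (s in seq_along(labelsets))
    if (!any(labelsets[[s]]$data == compartment))
      stop("compartment ", compartment, " empty in subject ", s)
  if (is.null(grid)) grid <- common_average_grid(labelsets)
  trunc_mm <- trunc_vox * min(grid$spacing)
  acc <- array(0, grid$dim)
  for (l in labelsets) {
    sdf <- signed_distance(l, value = compartment, trunc = trunc_mm)
    r <- resample_to_grid(sdf, grid, "linear", fill = trunc_mm)
    acc <- acc + r$data
  }
  mean_sdf <- new_volume3d(acc / length(labelsets), grid$spacing, grid$origin,
                           grid$orientation)
  if (method == "wrap")
    wrap_mesh_to_sdf(mean_sdf, n_theta = n_theta, n_rings = n_rings)
  else
    mesh_from_sdf(mean_sdf, mesh_spacing = mesh_spacing, smoothing = smoothing)
}

#' Build the average multi-compartment shape model
#'
#' Pose-aligns the training label volumes, fuzzy-averages each of the six
#' compartments, and recenters the assembled mean mesh so its centroid sits
#' at the reference-frame origin.
#'
#' @param labelsets list of `label_volume`s (unaligned).
#' @param mesh_spacing iso-surface grid spacing in mm for the mean mesh
#'   (controls triangle budget per compartment).
#' @param trunc_vox signed-distance truncation, in voxels.
#' @return object of class `shape_model`: `mean_mesh` (an `mc_mesh` centered
#'   at the origin), `center` (world centroid removed), `align` (training
#'   alignment transforms), `meta`.
#' @export
build_shape_model <- function(labelsets, mesh_spacing = 4, trunc_vox = 10) {
  al <- align_training_set(labelsets)
  grid <- common_average_grid(al$aligned)
  parts <- lapply(1:6, function(cc)
    fuzzy_average_labels(al$aligned, cc, grid = grid, trunc_vox = trunc_vox,
                         mesh_spacing = mesh_spacing))
  mc <- new_mc_mesh(parts)
  cen <- mesh_centroid(mc)
  mc$vertices <- sweep(mc$vertices, 2, cen)
  structure(list(mean_mesh = mc, center = cen, align = al$transforms,
                 meta = list(n_subjects = length(labelsets),
                             mesh_spacing = mesh_spacing,
                             trunc_vox = trunc_vox)),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf("<shape_model> mean mesh: %d vertices, %d triangles; %d training subjects\n",
              nrow(x$mean_mesh$vertices), nrow(x$mean_mesh$triangles),
              x$meta$n_subjects))
  invisible(x)
}

#' Training-time correspondence by model adaptation to label volumes
#'
#' Adapts the mean mesh to each subject's (pose-aligned) label volume with a
#' simple gradient feature on the binary compartment masks: a rigid stage per
#' compartment followed by free-form deformation.  All outputs share the mean
#' mesh topology, establishing vertex correspondence across the training set.
#'
#' @param model a `shape_model`.
#' @param labelsets list of pose-aligned `label_volume`s.
#' @param alpha shape-deviation weight during free-form deformation.
#' @param rigid_iters,ff_iters iteration caps for the two stages.
#' @param search_l,search_step profile half-length and sample step in mm.
#' @return list of `mc_mesh` objects, one per subject, identical topology.
#' @export
establish_correspondence <- function(model, labelsets, alpha = 1,
                                     rigid_iters = 10, ff_iters = 20,
                                     search_l = 12, search_step = 1.5) {
  lapply(seq_along(labelsets), function(s) {
    labels <- labelsets[[s]]
    sub_cen <- label_centroids(labels)
    mod_cen <- t(vapply(1:6, function(cc)
      mesh_centroid(mc_compartment(model$mean_mesh, cc)), numeric(3)))
    pose <- kabsch_rigid(mod_cen, sub_cen)
    parts <- vector("list", 6)
    for (cc in 1:6) {
      maskvol <- new_volume3d((labels$data == cc) * 1, labels$spacing,
                              labels$origin, labels$orientation)
      detect <- function(mesh) detect_targets_gradient(mesh, maskvol,
                                                       L = search_l,
                                                       step = search_step)
      mean_comp <- mc_compartment(model$mean_mesh, cc)
      res <- adapt_mesh_engine(mean_comp, pose, detect, alpha = alpha,
                               rigid_iters = rigid_iters, ff_iters = ff_iters)
      if (res$fraction_detected < 0.5)
        stop("correspondence failed for subject ", s, " compartment ", cc,
             ": boundary found for only ",
             round(100 * res$fraction_detected), "% of triangles")
      parts[[cc]] <- res$mesh
    }
    new_mc_mesh(parts)
  })
}
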