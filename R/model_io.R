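# Serialization: ASCII PLY meshes with a per-triangle compartment property,
# and the trained-model bundle directory (mean mesh + feature model + GHT
# r-table + manifest, all text formats).

#' Write a mesh as ASCII PLY
#'
#' Multi-compartment meshes carry a per-face integer property `compartment`.
#'
#' @param mesh `triangle_mesh` or `mc_mesh`.
#' @param path output `.ply` path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  nv <- nrow(mesh$vertices); nt <- nrow(mesh$triangles)
  has_comp <- inherits(mesh, "mc_mesh")
  hdr <- c("ply", "format ascii 1.0",
           "comment paraseg multi-compartment surface",
           sprintf("element vertex %d", nv),
           "property float x", "property float y", "property float z",
           sprintf("element face %d", nt),
           "property list uchar int vertex_indices",
           if (has_comp) "property int compartment",
           "end_header")
  vlines <- sprintf("%.6f %.6f %.6f", mesh$vertices[, 1], mesh$vertices[, 2],
                    mesh$vertices[, 3])
  t0 <- mesh$triangles - 1L
  flines <- if (has_comp)
    sprintf("3 %d %d %d %d", t0[, 1], t0[, 2], t0[, 3], mesh$triangle_labels)
  else sprintf("3 %d %d %d", t0[, 1], t0[, 2], t0[, 3])
  writeLines(c(hdr, vlines, flines), path)
  invisible(path)
}

#' Read an ASCII PLY mesh
#'
#' @param path `.ply` file written by [write_ply()] (ASCII format).
#' @return `triangle_mesh`, or `mc_mesh` when a `compartment` face property
#'   is present.
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply") stop("not a PLY file: ", path)
  if (!grepl("ascii", lines[2])) stop("only ASCII PLY is supported")
  hdr_end <- match("end_header", lines)
  hdr <- lines[seq_len(hdr_end)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nt <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)))
  has_comp <- any(grepl("property int compartment", hdr))
  vl <- lines[hdr_end + seq_len(nv)]
  fl <- lines[hdr_end + nv + seq_len(nt)]
  verts <- matrix(as.numeric(unlist(strsplit(vl, " "))), nv, 3, byrow = TRUE)
  fm <- matrix(as.integer(unlist(strsplit(fl, " "))), nt, byrow = TRUE,
               ncol = if (has_comp) 5 else 4)
  tris <- fm[, 2:4] + 1L
  if (has_comp) {
    labels <- fm[, 5]
    parts <- lapply(1:6, function(cc) {
      sel <- labels == cc
      t <- tris[sel, , drop = FALSE]
      vid <- sort(unique(as.vector(t)))
      remap <- integer(nv); remap[vid] <- seq_along(vid)
      new_triangle_mesh(verts[vid, , drop = FALSE], matrix(remap[t], ncol = 3))
    })
    new_mc_mesh(parts)
  } else new_triangle_mesh(verts, tris)
}

#' Train the complete segmentation model
#'
#' Runs the training pipeline: rigid pose alignment of the training label
#' volumes, fuzzy shape averaging into the mean multi-compartment mesh,
#' training-time correspondence, dual-channel feature training on the native
#' images, and generalized-Hough model construction.
#'
#' @param subjects list of training observations, each a list with `water`,
#'   `fat` (`volume3d`) and `labels` (`label_volume`).
#' @param mesh_spacing mean-mesh iso-grid spacing (mm).
#' @param feature_l,feature_step boundary-search profile geometry (mm).
#' @return object of class `trained_model` with `shape_model`,
#'   `feature_model`, `ght_model`.
#' @export
train_model <- function(subjects, mesh_spacing = 4, feature_l = 10,
                        feature_step = 1) {
  if (length(subjects) < 2) stop("training needs at least 2 observations")
  labelsets <- lapply(subjects, `[[`, "labels")
  al <- align_training_set(labelsets)
  model <- build_shape_model(labelsets, mesh_spacing = mesh_spacing)
  corr <- establish_correspondence(model, al$aligned)
  # map correspondence meshes back to each subject's native frame for
  # feature training on the original images
  feat_subjects <- lapply(seq_along(subjects), function(s) {
    inv <- invert_rigid(al$transforms[[s]])
    mesh <- corr[[s]]
    mesh$vertices <- apply_rigid(inv, mesh$vertices)
    list(water = subjects[[s]]$water, fat = subjects[[s]]$fat, mesh = mesh)
  })
  fm <- train_features(model, feat_subjects, L = feature_l, step = feature_step)
  ght <- build_ght_model(model)
  structure(list(shape_model = model, feature_model = fm, ght_model = ght,
                 correspondence = corr,
                 meta = list(n_observations = length(subjects),
                             mesh_spacing = mesh_spacing)),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %d training observations; mean mesh %d triangles\n",
              x$meta$n_observations, nrow(x$shape_model$mean_mesh$triangles)))
  invisible(x)
}

#' Save a trained model bundle to a directory
#'
#' Layout: `mean_mesh.ply` (ASCII, compartment-labeled), `features.json`
#' (catalogues + per-triangle selections), `ght.json` (r-table) and
#' `manifest.json`.
#'
#' @param model a `trained_model`.
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ply(model$shape_model$mean_mesh, file.path(dir, "mean_mesh.ply"))
  fm <- model$feature_model
  jsonlite::write_json(list(
    catalogue = fm$catalogue, water_id = fm$water_id, fat_id = fm$fat_id,
    weight_water = fm$weight_water, residual_water = fm$residual_water,
    residual_fat = fm$residual_fat, L = fm$L, step = fm$step,
    gamma_frac = fm$gamma_frac, n_triangles = fm$n_triangles),
    file.path(dir, "features.json"), digits = NA, auto_unbox = TRUE)
  g <- model$ght_model
  jsonlite::write_json(list(rtable = g$rtable, n_az = g$n_az, n_el = g$n_el,
                            gradient_threshold = g$gradient_threshold,
                            n_offsets = g$n_offsets),
                       file.path(dir, "ght.json"), digits = NA,
                       auto_unbox = TRUE)
  manifest <- list(package = "paraseg",
                   n_observations = model$meta$n_observations,
                   mesh_spacing = model$meta$mesh_spacing,
                   center = model$shape_model$center)
  if (!is.null(model$meta$inputs)) manifest$inputs <- model$meta$inputs
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Load a trained model bundle
#'
#' @param dir directory written by [save_model()].
#' @return a `trained_model` (without training-time correspondence meshes).
#' @export
load_model <- function(dir) {
  mean_mesh <- read_ply(file.path(dir, "mean_mesh.ply"))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  fj <- jsonlite::read_json(file.path(dir, "features.json"), simplifyVector = TRUE)
  fm <- structure(list(
    catalogue = lapply(fj$catalogue, as.data.frame),
    water_id = fj$water_id, fat_id = fj$fat_id,
    weight_water = fj$weight_water, residual_water = fj$residual_water,
    residual_fat = fj$residual_fat, L = fj$L, step = fj$step,
    gamma_frac = fj$gamma_frac, n_triangles = fj$n_triangles),
    class = "feature_model")
  gj <- jsonlite::read_json(file.path(dir, "ght.json"), simplifyVector = TRUE)
  ght <- structure(list(rtable = lapply(gj$rtable, function(m) matrix(unlist(m), ncol = 3)),
                        n_az = gj$n_az, n_el = gj$n_el,
                        gradient_threshold = gj$gradient_threshold,
                        n_offsets = gj$n_offsets),
                   class = "ght_model")
  sm <- structure(list(mean_mesh = mean_mesh, center = man$center,
                       align = NULL,
                       meta = list(n_subjects = man$n_observations,
                                   mesh_spacing = man$mesh_spacing)),
                  class = "shape_model")
  structure(list(shape_model = sm, feature_model = fm, ght_model = ght,
                 meta = list(n_observations = man$n_observations,
                             mesh_spacing = man$mesh_spacing)),
            class = "trained_model")
}
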