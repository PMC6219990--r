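#' @useDynLib paraseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

COMPARTMENT_NAMES <- c(
  "right_erector_spinae", "left_erector_spinae",
  "right_quadratus_lumborum", "left_quadratus_lumborum",
  "right_psoas", "left_psoas")

#' Construct a 3-D scalar volume
#'
#' A `volume3d` couples a scalar voxel array with its grid geometry: voxel
#' spacing (mm), the world coordinate of the first voxel center, and a 3x3
#' direction matrix with orthonormal columns.  World coordinates of voxel
#' (i, j, k) (0-based) are `origin + orientation %*% (spacing * c(i, j, k))`.
#'
#' @param data numeric 3-D array.
#' @param spacing numeric length-3, mm per voxel step, strictly positive.
#' @param origin world position (mm) of the center of voxel (0, 0, 0).
#' @param orientation 3x3 direction matrix, orthonormal columns.
#' @return object of class `volume3d`.
#' @export
new_volume3d <- function(data, spacing, origin = c(0, 0, 0),
                         orientation = diag(3)) {
  if (length(dim(data)) != 3L)
    stop("expected 3-D volume, got ", length(dim(data)), "-D data")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive values")
  orientation <- matrix(as.numeric(orientation), 3, 3)
  if (max(abs(crossprod(orientation) - diag(3))) > 1e-6)
    stop("orientation columns must be orthonormal")
  structure(list(data = data, spacing = spacing,
                 origin = as.numeric(origin), orientation = orientation),
            class = "volume3d")
}

#' Construct an integer label volume
#'
#' Same geometry model as [new_volume3d()] but voxel values are integer
#' compartment labels: 0 background, 1-6 the muscle compartments in the fixed
#' order right/left erector spinae, right/left quadratus lumborum, right/left
#' psoas.
#'
#' @inheritParams new_volume3d
#' @return object of class `label_volume` (also `volume3d`).
#' @export
new_label_volume <- function(data, spacing, origin = c(0, 0, 0),
                             orientation = diag(3)) {
  vals <- unique(as.vector(data))
  bad <- vals[!(vals %in% 0:6)]
  if (length(bad))
    stop("label volume contains values outside 0..6: ",
         paste(sort(bad), collapse = ", "))
  storage.mode(data) <- "integer"
  v <- new_volume3d(data, spacing, origin, orientation)
  class(v) <- c("label_volume", class(v))
  v
}

vol_dim <- function(v) dim(v$data)

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm\n",
              class(x)[1], paste(vol_dim(x), collapse = "x"),
              paste(format(x$spacing, digits = 3), collapse = "x")))
  invisible(x)
}

#' Grid geometry of a volume
#' @param v a `volume3d`.
#' @return list with `dim`, `spacing`, `origin`, `orientation`.
#' @export
vol_geometry <- function(v)
  list(dim = vol_dim(v), spacing = v$spacing, origin = v$origin,
       orientation = v$orientation)

same_geometry <- function(a, b, tol = 1e-6) {
  identical(vol_dim(a), vol_dim(b)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol &&
    max(abs(a$orientation - b$orientation)) < tol
}

#' Map 0-based voxel indices to world coordinates (mm)
#' @param v a `volume3d` or geometry list.
#' @param idx n x 3 matrix of continuous 0-based indices.
#' @return n x 3 matrix of world coordinates.
#' @export
index_to_world <- function(v, idx) {
  idx <- matrix(idx, ncol = 3)
  sweep(idx %*% (t(v$orientation) * v$spacing), 2, v$origin, "+")
}

#' Map world coordinates (mm) to continuous 0-based voxel indices
#' @param v a `volume3d` or geometry list.
#' @param pts n x 3 matrix of world coordinates.
#' @return n x 3 matrix of continuous indices.
#' @export
world_to_index <- function(v, pts) {
  pts <- matrix(pts, ncol = 3)
  sweep(sweep(pts, 2, v$origin, "-") %*% v$orientation, 2, v$spacing, "/")
}

vol_affine <- function(v) {
  aff <- diag(4)
  aff[1:3, 1:3] <- v$orientation %*% diag(v$spacing)
  aff[1:3, 4] <- v$origin
  aff
}

affine_to_geometry <- function(aff, dim) {
  m <- aff[1:3, 1:3]
  spacing <- sqrt(colSums(m^2))
  if (any(spacing <= 0)) stop("degenerate affine: zero-length column")
  list(dim = dim, spacing = spacing, origin = aff[1:3, 4],
       orientation = sweep(m, 2, spacing, "/"))
}

#' Read a NIfTI-1 volume
#'
#' Reads a 3-D NIfTI file, taking the grid geometry from the sform/qform
#' affine.  Files where neither transform is set are refused rather than
#' guessed at.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param labels read as a [new_label_volume()] (values checked against 0..6).
#' @return a `volume3d` or `label_volume`.
#' @export
read_volume <- function(path, labels = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected 3-D volume in ", path, ", got ", length(d), "-D image")
  hdr <- RNifti::niftiHeader(img)
  if (hdr$sform_code == 0 && hdr$qform_code == 0)
    stop("NIfTI file ", path, " has neither sform nor qform set; refusing to guess geometry")
  geo <- affine_to_geometry(unclass(RNifti::xform(img)), d)
  arr <- array(as.numeric(img), dim = d)
  if (labels) {
    if (any(abs(arr - round(arr)) > 1e-6))
      stop("non-integer values in label file ", path)
    new_label_volume(array(as.integer(round(arr)), d), geo$spacing,
                     geo$origin, geo$orientation)
  } else {
    new_volume3d(arr, geo$spacing, geo$origin, geo$orientation)
  }
}

#' Write a volume as NIfTI-1
#'
#' Signal volumes are stored as float32, label volumes as int16; the full
#' affine goes into the sform (and qform).
#'
#' @param v a `volume3d` or `label_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  img <- RNifti::asNifti(v$data)
  aff <- vol_affine(v)
  # sform only: assigning the qform as well makes RNifti renormalize the
  # quaternion representation and drop the voxel scaling
  RNifti::sform(img) <- structure(aff, code = 2L)
  dtype <- if (inherits(v, "label_volume")) "int16" else "float"
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Compute a proton-density fat-fraction map
#'
#' PDFF is the fat signal divided by the total (fat + water) signal, in
#' percent.  Voxels whose total signal falls below `floor_frac` times the
#' volume maximum of the total signal are treated as signal voids: their PDFF
#' is set to 0 and their count is attached as attribute `signal_void` (and
#' reported via a warning when nonzero).
#'
#' @param water,fat `volume3d` water and fat magnitude volumes on the same
#'   grid, values nonnegative.
#' @param floor_frac signal-void floor as a fraction of the maximum total
#'   signal.
#' @return `volume3d` with values in percent, range 0-100.
#' @export
compute_pdff_map <- function(water, fat, floor_frac = 1e-6) {
  if (!same_geometry(water, fat)) stop("water and fat volumes have mismatched geometry")
  if (any(water$data < 0) || any(fat$data < 0))
    stop("negative signal values in input volumes")
  total <- water$data + fat$data
  eps <- floor_frac * max(total)
  void <- total < eps
  pdff <- array(0, vol_dim(water))
  pdff[!void] <- 100 * fat$data[!void] / total[!void]
  out <- new_volume3d(pdff, water$spacing, water$origin, water$orientation)
  attr(out, "signal_void") <- sum(void)
  if (any(void))
    warning(sum(void), " signal-void voxel(s) set to PDFF 0")
  out
}

#' Resample a volume onto a target grid
#'
#' Interpolation happens in world space: each target voxel center is mapped
#' through both affines into the source grid.  Label volumes must use nearest
#' mode; samples falling outside the source grid get `fill`.
#'
#' @param v source `volume3d`.
#' @param target a `volume3d` or geometry list (from [vol_geometry()]).
#' @param mode `"linear"` or `"nearest"`.
#' @param fill value for target voxels outside the source grid.
#' @return resampled volume on the target grid.
#' @export
resample_to_grid <- function(v, target, mode = c("linear", "nearest"),
                             fill = 0) {
  mode <- match.arg(mode)
  if (inherits(v, "label_volume") && mode == "linear")
    stop("linear interpolation is not valid for label volumes; use nearest")
  tg <- if (inherits(target, "volume3d")) vol_geometry(target) else target
  d <- tg$dim
  idx <- as.matrix(expand.grid(0:(d[1] - 1), 0:(d[2] - 1), 0:(d[3] - 1)))
  world <- index_to_world(tg, idx)
  src_idx <- world_to_index(v, world)
  if (mode == "linear") {
    r <- cpp_trilinear(as.numeric(v$data), vol_dim(v), src_idx)
    vals <- r$values
    vals[!r$inside] <- fill
  } else {
    ri <- round(src_idx)
    ok <- ri[, 1] >= 0 & ri[, 1] <= vol_dim(v)[1] - 1 &
      ri[, 2] >= 0 & ri[, 2] <= vol_dim(v)[2] - 1 &
      ri[, 3] >= 0 & ri[, 3] <= vol_dim(v)[3] - 1
    vals <- rep(fill, nrow(ri))
    lin <- ri[ok, 1] + vol_dim(v)[1] * (ri[ok, 2] + vol_dim(v)[2] * ri[ok, 3])
    vals[ok] <- as.numeric(v$data)[lin + 1]
  }
  arr <- array(vals, d)
  if (inherits(v, "label_volume"))
    new_label_volume(array(as.integer(arr), d), tg$spacing, tg$origin,
                     tg$orientation)
  else
    new_volume3d(arr, tg$spacing, tg$origin, tg$orientation)
}

#' Gaussian smoothing of a volume
#'
#' Separable Gaussian with per-axis sigma given in voxels; kernel truncated at
#' three sigma.  Used for image pyramids and gradient computation.
#'
#' @param v a `volume3d`.
#' @param sigma_vox scalar or length-3 sigma in voxel units.
#' @return smoothed `volume3d`.
#' @export
smooth_volume <- function(v, sigma_vox) {
  sigma_vox <- rep(sigma_vox, length.out = 3)
  dat <- as.numeric(v$data)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    k <- exp(-((-half:half)^2) / (2 * s^2))
    k <- k / sum(k)
    dat <- cpp_convolve_axis(dat, vol_dim(v), k, ax - 1L)
  }
  new_volume3d(array(dat, vol_dim(v)), v$spacing, v$origin, v$orientation)
}

#' Downsample a volume by an integer factor
#'
#' Gaussian pre-smoothing (sigma = factor/2 voxels) followed by world-space
#' linear resampling onto a grid with `factor`-times coarser spacing.
#'
#' @param v a `volume3d`.
#' @param factor integer downsampling factor (1 returns the input).
#' @return coarser `volume3d`.
#' @export
downsample_volume <- function(v, factor) {
  if (factor == 1) return(v)
  sm <- smooth_volume(v, factor / 2)
  d <- pmax(2L, as.integer(ceiling(vol_dim(v) / factor)))
  tg <- list(dim = d, spacing = v$spacing * factor, origin = v$origin,
             orientation = v$orientation)
  resample_to_grid(sm, tg, "linear")
}

#' Signed Euclidean distance field of a binary mask
#'
#' Positive outside the mask, negative inside, in mm; computed with an exact
#' separable distance transform honoring anisotropic spacing.  Optionally
#' truncated at `trunc` mm.
#'
#' @param v a `volume3d`/`label_volume`.
#' @param value voxels equal to `value` form the mask (default any nonzero).
#' @param trunc optional truncation distance in mm.
#' @return `volume3d` of signed distances.
#' @export
signed_distance <- function(v, value = NULL, trunc = NULL) {
  mask <- if (is.null(value)) v$data != 0 else v$data == value
  if (!any(mask)) stop("mask is empty")
  d_out <- sqrt(cpp_edt_sq(as.vector(mask), vol_dim(v), v$spacing))
  d_in <- sqrt(cpp_edt_sq(as.vector(!mask), vol_dim(v), v$spacing))
  sdf <- d_out - d_in
  if (!is.null(trunc)) sdf <- pmin(pmax(sdf, -trunc), trunc)
  new_volume3d(array(sdf, vol_dim(v)), v$spacing, v$origin, v$orientation)
}
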