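# Generalized Hough transform for translation-only structure localization:
# the r-table maps quantized surface-normal directions to offsets from
# boundary points to the model reference point (the mean-mesh centroid).

direction_bins <- function(dirs, n_az = 12, n_el = 6) {
  dirs <- matrix(dirs, ncol = 3)
  nn <- sqrt(rowSums(dirs^2))
  d <- dirs / pmax(nn, 1e-300)
  az <- atan2(d[, 2], d[, 1])            # [-pi, pi]
  iaz <- pmin(floor((az + pi) / (2 * pi) * n_az), n_az - 1)
  iel <- pmin(floor((d[, 3] + 1) / 2 * n_el), n_el - 1)
  as.integer(iel * n_az + iaz + 1)
}

#' Build a generalized Hough transform model from the mean mesh
#'
#' The r-table is built from the mean-mesh triangle centroids and outward
#' normals: each quantized normal direction stores the offsets from those
#' boundary points to the model reference point (the mesh centroid, i.e. the
#' origin of the model frame).
#'
#' @param model a `shape_model`.
#' @param n_az,n_el azimuth/elevation direction quantization.
#' @param gradient_threshold fraction of the maximum gradient magnitude a
#'   voxel must exceed to vote at localization time.
#' @return object of class `ght_model`.
#' @export
build_ght_model <- function(model, n_az = 12, n_el = 6,
                            gradient_threshold = 0.3) {
  mesh <- model$mean_mesh
  for (cc in 1:6)
    if (!mesh_is_closed(mc_compartment(mesh, cc)))
      stop("compartment ", cc, " of the mean mesh is not closed")
  g <- triangle_geometry(mesh)
  cen <- sweep(g$centroids, 2, mesh_centroid(mesh))  # ref point at centroid
  bins <- direction_bins(g$normals, n_az, n_el)
  rtable <- split.data.frame(-cen, bins)
  if (!length(rtable)) stop("degenerate mesh: empty r-table")
  structure(list(rtable = lapply(rtable, as.matrix), n_az = n_az,
                 n_el = n_el, gradient_threshold = gradient_threshold,
                 n_offsets = nrow(cen)),
            class = "ght_model")
}

#' @export
print.ght_model <- function(x, ...) {
  cat(sprintf("<ght_model> %d offsets in %d direction bins\n",
              x$n_offsets, length(x$rtable)))
  invisible(x)
}

gradient_volume <- function(v) {
  d <- vol_dim(v)
  a <- v$data
  g <- vector("list", 3)
  for (ax in 1:3) {
    hi <- a; lo <- a
    idx_hi <- pmin(seq_len(d[ax]) + 1, d[ax])
    idx_lo <- pmax(seq_len(d[ax]) - 1, 1)
    if (ax == 1) { hi <- a[idx_hi, , , drop = FALSE]; lo <- a[idx_lo, , , drop = FALSE] }
    if (ax == 2) { hi <- a[, idx_hi, , drop = FALSE]; lo <- a[, idx_lo, , drop = FALSE] }
    if (ax == 3) { hi <- a[, , idx_hi, drop = FALSE]; lo <- a[, , idx_lo, drop = FALSE] }
    g[[ax]] <- (hi - lo) / (2 * v$spacing[ax])
  }
  g
}

#' Localize the model in an unseen image
#'
#' Voxels whose gradient magnitude exceeds the threshold fraction of the
#' image maximum vote into a 3-D accumulator with the offsets stored for
#' their quantized gradient direction.  The accumulator is smoothed with a
#' one-cell Gaussian; the peak (refined by the weighted centroid of its 3^3
#' neighborhood) is returned as the estimated model centroid.
#'
#' @param water,fat image channels.
#' @param ght a `ght_model`.
#' @param step accumulator cell spacing in mm.
#' @param channel gradient source: `"fat"` (default), `"water"` or `"max"`
#'   (the voxelwise stronger of the two).
#' @param smooth_sigma_vox Gaussian pre-smoothing of the image in voxels.
#' @return list with `translation` (estimated model centroid, mm),
#'   `confidence` (peak votes / total votes) and `votes` (total).
#' @export
locate <- function(water, fat, ght, step = 4, channel = c("fat", "water", "max"),
                   smooth_sigma_vox = 1) {
  channel <- match.arg(channel)
  pick <- function(v) smooth_volume(v, smooth_sigma_vox)
  gv <- switch(channel,
               fat = gradient_volume(pick(fat)),
               water = gradient_volume(pick(water)),
               max = {
                 gf <- gradient_volume(pick(fat)); gw <- gradient_volume(pick(water))
                 mf <- sqrt(gf[[1]]^2 + gf[[2]]^2 + gf[[3]]^2)
                 mw <- sqrt(gw[[1]]^2 + gw[[2]]^2 + gw[[3]]^2)
                 use_f <- mf >= mw
                 lapply(1:3, function(ax) ifelse(use_f, gf[[ax]], gw[[ax]]))
               })
  gmag <- sqrt(gv[[1]]^2 + gv[[2]]^2 + gv[[3]]^2)
  gmax <- max(gmag)
  if (gmax <= 0) stop("no structure: image gradient is zero everywhere")
  sel <- which(gmag > ght$gradient_threshold * gmax)
  if (!length(sel)) stop("no structure: no voxel exceeds the gradient threshold")
  d <- vol_dim(fat)
  ai <- arrayInd(sel, d) - 1
  pos <- index_to_world(fat, ai)
  # gradient vector in world coordinates
  gidx <- cbind(gv[[1]][sel], gv[[2]][sel], gv[[3]][sel])
  gw <- gidx %*% t(fat$orientation)
  bins <- direction_bins(gw, ght$n_az, ght$n_el)

  lo <- apply(index_to_world(fat, rbind(c(0, 0, 0), d - 1)), 2, min) - 2 * step
  hi <- apply(index_to_world(fat, rbind(c(0, 0, 0), d - 1)), 2, max) + 2 * step
  ad <- as.integer(ceiling((hi - lo) / step)) + 1L
  acc <- numeric(prod(ad))
  total <- 0
  for (b in names(ght$rtable)) {
    vb <- which(bins == as.integer(b))
    if (!length(vb)) next
    off <- ght$rtable[[b]]
    no <- nrow(off)
    votes <- pos[rep(vb, each = no), , drop = FALSE] +
      off[rep(seq_len(no), length(vb)), , drop = FALSE]
    ci <- floor(sweep(votes, 2, lo) / step + 0.5)
    ok <- ci[, 1] >= 0 & ci[, 1] < ad[1] & ci[, 2] >= 0 & ci[, 2] < ad[2] &
      ci[, 3] >= 0 & ci[, 3] < ad[3]
    ci <- ci[ok, , drop = FALSE]
    lin <- ci[, 1] + ad[1] * (ci[, 2] + ad[2] * ci[, 3]) + 1
    tb <- tabulate(lin, nbins = prod(ad))
    acc <- acc + tb
    total <- total + nrow(ci)
  }
  if (total == 0) stop("no structure: all votes fell outside the accumulator")
  k <- exp(-(-2:2)^2 / 2); k <- k / sum(k)
  sm <- acc
  for (ax in 0:2) sm <- cpp_convolve_axis(sm, ad, k, ax)
  pk <- which.max(sm)
  pk_idx <- arrayInd(pk, ad) - 1
  # weighted centroid of the 3^3 neighborhood, in accumulator cells
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nbi <- sweep(nb, 2, as.numeric(pk_idx), "+")
  ok <- nbi[, 1] >= 0 & nbi[, 1] < ad[1] & nbi[, 2] >= 0 & nbi[, 2] < ad[2] &
    nbi[, 3] >= 0 & nbi[, 3] < ad[3]
  nbi <- nbi[ok, , drop = FALSE]
  wv <- sm[nbi[, 1] + ad[1] * (nbi[, 2] + ad[2] * nbi[, 3]) + 1]
  cen_cell <- colSums(nbi * wv) / sum(wv)
  translation <- lo + cen_cell * step
  list(translation = as.numeric(translation),
       confidence = acc[pk] / total, votes = total)
}
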