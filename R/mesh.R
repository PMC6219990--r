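#' Construct a triangle mesh
#'
#' Vertices are world coordinates in mm; triangles are 1-based vertex index
#' triples with consistent outward winding (counter-clockwise seen from
#' outside, so the divergence-theorem volume is positive for a closed surface).
#'
#' @param vertices n x 3 numeric matrix.
#' @param triangles m x 3 integer matrix, 1-based.
#' @return object of class `triangle_mesh`.
#' @export
new_triangle_mesh <- function(vertices, triangles) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  triangles <- matrix(as.integer(triangles), ncol = 3)
  if (nrow(triangles) && (min(triangles) < 1 || max(triangles) > nrow(vertices)))
    stop("triangle indices out of range")
  structure(list(vertices = vertices, triangles = triangles),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

#' Construct a six-compartment surface model
#'
#' Bundles one triangle mesh whose triangles (and vertices) are partitioned
#' into six closed compartment surfaces, labeled 1-6 in the fixed compartment
#' order.  Compartments do not share vertices.
#'
#' @param meshes list of six closed `triangle_mesh` objects, in label order.
#' @return object of class `mc_mesh`.
#' @export
new_mc_mesh <- function(meshes) {
  if (length(meshes) != 6L) stop("expected six compartment meshes")
  verts <- NULL; tris <- NULL; labels <- integer(0)
  off <- 0L
  for (cc in 1:6) {
    m <- meshes[[cc]]
    verts <- rbind(verts, m$vertices)
    tris <- rbind(tris, m$triangles + off)
    labels <- c(labels, rep(cc, nrow(m$triangles)))
    off <- off + nrow(m$vertices)
  }
  structure(list(vertices = verts, triangles = tris,
                 triangle_labels = labels),
            class = c("mc_mesh", "triangle_mesh"))
}

#' @export
print.mc_mesh <- function(x, ...) {
  cat(sprintf("<mc_mesh> %d vertices, %d triangles, 6 compartments\n",
              nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

#' Extract one compartment as a standalone mesh
#'
#' @param mc an `mc_mesh`.
#' @param compartment label 1-6.
#' @return `triangle_mesh` with attribute `vertex_ids` giving the row indices
#'   of its vertices in the parent mesh.
#' @export
mc_compartment <- function(mc, compartment) {
  sel <- mc$triangle_labels == compartment
  if (!any(sel)) stop("compartment ", compartment, " not present")
  tris <- mc$triangles[sel, , drop = FALSE]
  vid <- sort(unique(as.vector(tris)))
  remap <- integer(nrow(mc$vertices))
  remap[vid] <- seq_along(vid)
  m <- new_triangle_mesh(mc$vertices[vid, , drop = FALSE],
                         matrix(remap[tris], ncol = 3))
  attr(m, "vertex_ids") <- vid
  m
}

#' Replace the vertices of a mesh
#' @param mesh a `triangle_mesh` or `mc_mesh`.
#' @param vertices replacement n x 3 matrix.
#' @return mesh with new vertex positions, same topology.
#' @export
set_vertices <- function(mesh, vertices) {
  stopifnot(nrow(vertices) == nrow(mesh$vertices))
  mesh$vertices <- matrix(as.numeric(vertices), ncol = 3)
  mesh
}

mesh_edges <- function(mesh) {
  t <- mesh$triangles
  e <- rbind(t[, 1:2], t[, 2:3], t[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Check that a mesh is closed (watertight)
#'
#' Every undirected edge must be used by exactly two triangles, once in each
#' direction.
#'
#' @param mesh a `triangle_mesh`.
#' @return logical.
#' @export
mesh_is_closed <- function(mesh) {
  t <- mesh$triangles
  if (!nrow(t)) return(FALSE)
  e <- rbind(t[, 1:2], t[, 2:3], t[, c(3, 1)])
  key_und <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key_und)
  if (any(cnt != 2)) return(FALSE)
  # each direction exactly once
  key_dir <- paste(e[, 1], e[, 2])
  !any(duplicated(key_dir))
}

triangle_geometry <- function(mesh) {
  v <- mesh$vertices; t <- mesh$triangles
  p0 <- v[t[, 1], , drop = FALSE]
  p1 <- v[t[, 2], , drop = FALSE]
  p2 <- v[t[, 3], , drop = FALSE]
  e1 <- p1 - p0; e2 <- p2 - p0
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area2 <- sqrt(rowSums(n^2))
  list(centroids = (p0 + p1 + p2) / 3,
       normals = n / pmax(area2, 1e-300),
       areas = area2 / 2)
}

#' Per-vertex outward normals (area-weighted)
#' @param mesh a closed `triangle_mesh`.
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  g <- triangle_geometry(mesh)
  nv <- nrow(mesh$vertices)
  w <- g$normals * g$areas
  idx <- c(mesh$triangles[, 1], mesh$triangles[, 2], mesh$triangles[, 3],
           seq_len(nv))
  n <- rowsum(rbind(w, w, w, matrix(0, nv, 3)), idx)
  n / pmax(sqrt(rowSums(n^2)), 1e-300)
}

#' Enclosed volume of a closed mesh
#'
#' Divergence-theorem signed volume; raises an error for open meshes or
#' inward (negative) orientation.
#'
#' @param mesh a closed, outward-oriented `triangle_mesh` (or `mc_mesh`, in
#'   which case the sum over compartments is returned).
#' @return volume in cm^3.
#' @export
mesh_volume <- function(mesh) {
  if (!mesh_is_closed(mesh)) stop("mesh is not closed")
  vol <- mesh_volume_signed(mesh)
  if (vol < 0) stop("mesh orientation is inward (negative signed volume)")
  vol
}

mesh_volume_signed <- function(mesh) {
  v <- mesh$vertices; t <- mesh$triangles
  p0 <- v[t[, 1], , drop = FALSE]
  p1 <- v[t[, 2], , drop = FALSE]
  p2 <- v[t[, 3], , drop = FALSE]
  det <- p0[, 1] * (p1[, 2] * p2[, 3] - p1[, 3] * p2[, 2]) -
    p0[, 2] * (p1[, 1] * p2[, 3] - p1[, 3] * p2[, 1]) +
    p0[, 3] * (p1[, 1] * p2[, 2] - p1[, 2] * p2[, 1])
  sum(det) / 6 / 1000  # mm^3 -> cm^3
}

mesh_centroid <- function(mesh) {
  g <- triangle_geometry(mesh)
  colSums(g$centroids * g$areas) / sum(g$areas)
}

#' Laplacian smoothing with volume preservation
#'
#' Umbrella-operator smoothing; after each pass the mesh is rescaled about its
#' centroid so the enclosed volume is preserved (volume drift well below the
#' 2 percent contract).
#'
#' @param mesh a closed `triangle_mesh`.
#' @param iterations number of smoothing passes.
#' @param lambda step size in (0, 1].
#' @return smoothed mesh.
#' @export
smooth_mesh <- function(mesh, iterations = 5, lambda = 0.5) {
  if (iterations <= 0) return(mesh)
  e <- mesh_edges(mesh)
  nv <- nrow(mesh$vertices)
  adj_i <- c(e[, 1], e[, 2])
  adj_j <- c(e[, 2], e[, 1])
  deg <- tabulate(adj_i, nv)
  v0 <- mesh_volume_signed(mesh)
  V <- mesh$vertices
  for (it in seq_len(iterations)) {
    nb <- rowsum(rbind(V[adj_j, , drop = FALSE], matrix(0, nv, 3)),
                 c(adj_i, seq_len(nv)))
    V <- V + lambda * (nb / pmax(deg, 1) - V)
    m <- set_vertices(mesh, V)
    v1 <- mesh_volume_signed(m)
    if (v1 > 1e-12 && v0 > 1e-12) {
      cen <- mesh_centroid(m)
      s <- (v0 / v1)^(1 / 3)
      V <- sweep(sweep(V, 2, cen, "-") * s, 2, cen, "+")
    }
  }
  set_vertices(mesh, V)
}

#' Voxelize a multi-compartment mesh into a label volume
#'
#' A voxel receives label c when its center lies inside compartment c (ray
#' parity; boundary-grazing centers count as inside).  Where adapted
#' compartments overlap, the smallest compartment id wins and a warning
#' reports the number of contested voxels.
#'
#' @param mesh an `mc_mesh` (or single closed `triangle_mesh`, labeled 1).
#' @param grid a `volume3d` or geometry list defining the target grid.
#' @return a `label_volume`.
#' @export
voxelize <- function(mesh, grid) {
  tg <- if (inherits(grid, "volume3d")) vol_geometry(grid) else grid
  comps <- if (inherits(mesh, "mc_mesh")) 1:6 else 1L
  lab <- array(0L, tg$dim)
  overlap <- 0L
  for (cc in comps) {
    m <- if (inherits(mesh, "mc_mesh")) mc_compartment(mesh, cc) else mesh
    if (!mesh_is_closed(m))
      stop("compartment ", cc, " is not a closed surface")
    idx <- world_to_index(tg, m$vertices)
    r <- cpp_voxelize(idx, m$triangles, tg$dim)
    mask <- array(r$mask, tg$dim)
    clash <- mask & lab != 0L
    overlap <- overlap + sum(clash)
    lab[mask & lab == 0L] <- cc
  }
  if (overlap > 0)
    warning(overlap, " voxel(s) claimed by several compartments; kept smallest id")
  out <- new_label_volume(lab, tg$spacing, tg$origin, tg$orientation)
  attr(out, "overlap_voxels") <- overlap
  out
}

#' Extract a compartment surface from a label volume
#'
#' Builds the signed distance field of the binary compartment mask,
#' optionally resamples it to an isotropic mesh-resolution grid, and extracts
#' the zero iso-surface with marching tetrahedra, followed by
#' volume-preserving Laplacian smoothing.
#'
#' @param labels a `label_volume`.
#' @param compartment label 1-6 (or any value present).
#' @param smoothing smoothing iterations (0 disables; `"marching"` only —
#'   the wrap method is intrinsically regularized).
#' @param method `"wrap"` (shrink-wrapped tube, fixed triangle budget,
#'   default) or `"marching"` (marching tetrahedra at grid resolution).
#' @param mesh_spacing iso-grid spacing in mm for `"marching"` (`NULL` =
#'   native grid); coarser values yield fewer triangles.
#' @param n_theta,n_rings mesh resolution for `"wrap"`.
#' @return closed `triangle_mesh` in world coordinates.
#' @export
extract_compartment_mesh <- function(labels, compartment, smoothing = 3,
                                     method = c("wrap", "marching"),
                                     mesh_spacing = NULL, n_theta = 22,
                                     n_rings = 23) {
  method <- match.arg(method)
  if (!any(labels$data == compartment))
    stop("compartment ", compartment, " absent from label volume")
  sdf <- signed_distance(labels, value = compartment)
  if (method == "wrap")
    wrap_mesh_to_sdf(sdf, n_theta = n_theta, n_rings = n_rings)
  else
    mesh_from_sdf(sdf, mesh_spacing = mesh_spacing, smoothing = smoothing)
}

#' Extract the zero iso-surface of a signed distance volume
#'
#' @param sdf `volume3d` of signed distances (negative inside).
#' @param mesh_spacing optional isotropic grid spacing (mm) to resample the
#'   field to before extraction, controlling triangle count.
#' @param smoothing Laplacian smoothing iterations applied to the result.
#' @return closed `triangle_mesh` in world coordinates.
#' @export
mesh_from_sdf <- function(sdf, mesh_spacing = NULL, smoothing = 3) {
  if (!is.null(mesh_spacing)) {
    # pad one coarse voxel so the surface never touches the new grid border
    d <- vol_dim(sdf)
    ext <- (d - 1) * sdf$spacing
    nd <- pmax(4L, as.integer(ceiling(ext / mesh_spacing)) + 3L)
    tg <- list(dim = nd, spacing = rep(mesh_spacing, 3),
               origin = sdf$origin - as.numeric(sdf$orientation %*% rep(mesh_spacing, 3)),
               orientation = sdf$orientation)
    sdf <- resample_to_grid(sdf, tg, "linear", fill = max(sdf$data))
  }
  r <- cpp_marching_tets(as.numeric(sdf$data), vol_dim(sdf), 0)
  if (nrow(r$vertices) == 0) stop("iso-surface is empty")
  verts <- index_to_world(sdf, r$vertices)
  m <- new_triangle_mesh(verts, r$triangles)
  if (mesh_volume_signed(m) < 0)
    m$triangles <- m$triangles[, c(1, 3, 2)]
  if (smoothing > 0) m <- smooth_mesh(m, smoothing)
  m
}

#' Shrink-wrap a tube mesh onto the zero level of a signed distance field
#'
#' Initializes a closed tapered-tube mesh from the second moments of the
#' interior voxels (principal axes and extents) and iteratively projects its
#' vertices onto the zero level set along the field gradient, with Laplacian
#' regularization, finishing with unregularized projection passes.  Produces
#' a well-shaped closed surface with a fixed, controllable triangle budget
#' (about `2 * n_theta * n_rings` triangles) — the mesh-resolution target
#' used for the compartment models.  Suited to the blob- and tube-like
#' genus-0 shapes of muscle compartments.
#'
#' @param sdf `volume3d` signed distance field (negative inside).
#' @param n_theta,n_rings tube mesh resolution.
#' @param iterations projection/regularization iterations.
#' @param lambda Laplacian regularization step.
#' @return closed `triangle_mesh` on the zero level set.
#' @export
wrap_mesh_to_sdf <- function(sdf, n_theta = 22, n_rings = 23,
                             iterations = 40, lambda = 0.3) {
  d <- vol_dim(sdf)
  idx <- which(sdf$data < 0)
  if (!length(idx)) stop("iso-surface is empty")
  ai <- arrayInd(idx, d) - 1
  W <- index_to_world(sdf, ai)
  cen <- colMeans(W)
  if (nrow(W) >= 4) {
    sv <- svd(crossprod(sweep(W, 2, cen)) / nrow(W) + diag(3) * 1e-9)
    U <- sv$u
    if (det(U) < 0) U[, 3] <- -U[, 3]
    P <- sweep(W, 2, cen) %*% U
    ext <- pmax(apply(abs(P), 2, stats::quantile, probs = 0.99),
                0.75 * sdf$spacing)
  } else {
    U <- diag(3)
    ext <- 0.75 * sdf$spacing
  }
  tube <- tube_mesh(0, 0, 1.2 * ext[2], 1.2 * ext[3], 2.6 * ext[1],
                    n_theta, n_rings)
  M <- U[, c(2, 3, 1)]  # tube z axis onto the first principal axis
  V <- sweep(tube$vertices %*% t(M), 2, cen, "+")
  mesh <- new_triangle_mesh(V, tube$triangles)
  if (mesh_volume_signed(mesh) < 0)
    mesh$triangles <- mesh$triangles[, c(1, 3, 2)]

  svals <- as.numeric(sdf$data)
  fill <- max(svals)
  samp <- function(pts) {
    r <- cpp_trilinear(svals, d, world_to_index(sdf, pts))
    v <- r$values
    v[!r$inside] <- fill
    v
  }
  h <- min(sdf$spacing) / 2
  cap <- 2 * max(sdf$spacing)
  e <- mesh_edges(mesh)
  nv <- nrow(V)
  adj_i <- c(e[, 1], e[, 2])
  adj_j <- c(e[, 2], e[, 1])
  deg <- tabulate(adj_i, nv)
  project <- function(V, step) {
    s0 <- samp(V)
    g <- matrix(0, nv, 3)
    for (dax in 1:3) {
      off <- c(0, 0, 0); off[dax] <- h
      g[, dax] <- (samp(sweep(V, 2, off, "+")) - samp(sweep(V, 2, off, "-"))) / (2 * h)
    }
    g <- g / pmax(sqrt(rowSums(g^2)), 1e-6)
    V - step * pmin(pmax(s0, -cap), cap) * g
  }
  for (it in seq_len(iterations)) {
    V <- project(V, 0.7)
    nb <- rowsum(rbind(V[adj_j, , drop = FALSE], matrix(0, nv, 3)),
                 c(adj_i, seq_len(nv)))
    V <- V + lambda * (nb / pmax(deg, 1) - V)
  }
  for (it in 1:8) V <- project(V, 0.9)
  set_vertices(mesh, V)
}

#' Shrink a mesh inward along vertex normals
#'
#' Every vertex moves inward by `distance` mm along its outward normal
#' (displacement clamped to 40 percent of the shortest incident edge so thin
#' regions cannot fold through themselves), followed by one light smoothing
#' pass.  Intended for peeling a thin epimuscular rim off adapted contours.
#'
#' @param mesh a closed `triangle_mesh` or `mc_mesh`.
#' @param distance shrink distance in mm, >= 0.
#' @return shrunk mesh of the same topology.
#' @export
shrink_mesh <- function(mesh, distance) {
  if (distance < 0) stop("shrink distance must be nonnegative")
  if (distance == 0) return(mesh)
  if (inherits(mesh, "mc_mesh")) {
    parts <- lapply(1:6, function(cc) shrink_mesh(mc_compartment(mesh, cc), distance))
    return(new_mc_mesh(parts))
  }
  v0 <- mesh_volume(mesh)
  m <- mesh
  remaining <- distance
  while (remaining > 1e-9) {
    d <- min(remaining, 1)
    remaining <- remaining - d
    nrm <- vertex_normals(m)
    m <- set_vertices(m, m$vertices - nrm * d)
    if (mesh_volume_signed(m) <= 0)
      stop("shrink distance inverts the compartment")
    m <- smooth_mesh(m, 1, lambda = 0.2)
  }
  v1 <- mesh_volume_signed(m)
  if (v1 <= 0) stop("shrink distance inverts the compartment")
  if (v1 >= v0) stop("shrink failed to reduce the volume")
  m
}
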