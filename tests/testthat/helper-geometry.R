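# Analytic meshes and small volumes used as independent oracles.

# lat-long sphere with outward winding
uv_sphere <- function(radius = 10, center = c(0, 0, 0), nu = 64, nv = 32) {
  phi <- seq(0, pi, length.out = nv + 2)[2:(nv + 1)]
  th <- seq(0, 2 * pi, length.out = nu + 1)[1:nu]
  verts <- matrix(0, nv * nu + 2, 3)
  for (i in seq_len(nv)) {
    rows <- (i - 1) * nu + seq_len(nu)
    verts[rows, 1] <- center[1] + radius * sin(phi[i]) * cos(th)
    verts[rows, 2] <- center[2] + radius * sin(phi[i]) * sin(th)
    verts[rows, 3] <- center[3] + radius * cos(phi[i])
  }
  pn <- nv * nu + 1  # north pole (z = +r)
  ps <- nv * nu + 2
  verts[pn, ] <- center + c(0, 0, radius)
  verts[ps, ] <- center - c(0, 0, radius)
  jn <- c(2:nu, 1)
  tris <- rbind(cbind(pn, seq_len(nu), jn),
                cbind(ps, (nv - 1) * nu + jn, (nv - 1) * nu + seq_len(nu)))
  for (i in seq_len(nv - 1)) {
    a <- (i - 1) * nu + seq_len(nu); b <- (i - 1) * nu + jn
    cc <- i * nu + seq_len(nu); d <- i * nu + jn
    tris <- rbind(tris, cbind(a, cc, b), cbind(b, cc, d))
  }
  m <- new_triangle_mesh(verts, tris)
  if (paraseg:::mesh_volume_signed(m) < 0) m$triangles <- m$triangles[, c(1, 3, 2)]
  m
}

# axis-aligned cube [lo, lo+edge]^3 as 12 outward triangles
cube_mesh <- function(lo = 0, edge = 10) {
  v <- as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1))) * edge + lo
  f <- rbind(c(1, 3, 2), c(2, 3, 4),   # z = lo face
             c(5, 6, 7), c(6, 8, 7),   # z = hi face
             c(1, 2, 5), c(2, 6, 5),   # y = lo
             c(3, 7, 4), c(4, 7, 8),   # y = hi
             c(1, 5, 3), c(3, 5, 7),   # x = lo
             c(2, 4, 6), c(4, 8, 6))   # x = hi
  m <- new_triangle_mesh(v, f)
  if (paraseg:::mesh_volume_signed(m) < 0) m$triangles <- m$triangles[, c(1, 3, 2)]
  m
}

# volume whose data is the signed distance to a sphere (analytic)
sphere_sdf_volume <- function(radius = 12, dim = c(40L, 40L, 40L),
                              spacing = c(1, 1, 1),
                              center_idx = (dim - 1) / 2) {
  idx <- as.matrix(expand.grid(0:(dim[1] - 1), 0:(dim[2] - 1), 0:(dim[3] - 1)))
  r <- sqrt(colSums((t(idx) - center_idx)^2 * spacing^2))
  new_volume3d(array(r - radius, dim), spacing)
}

# digitized sphere label volume (voxel centers within radius)
sphere_label_volume <- function(radius = 8, dim = c(24L, 24L, 24L),
                                spacing = c(1, 1, 1), label = 1L) {
  sdf <- sphere_sdf_volume(radius, dim, spacing)
  new_label_volume(array(as.integer(sdf$data < 0) * label, dim), spacing,
                   sdf$origin, sdf$orientation)
}

# small fast phantom: same fields of view as the default at half resolution
small_phantom_spec <- function(...) {
  phantom_spec(dim = c(36L, 55L, 37L), spacing = c(6.2, 4.0, 6.0), ...)
}
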