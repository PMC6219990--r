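# Rigid (rotation + translation) transform helpers.  A transform is a list
# with a 3x3 rotation R and length-3 translation t; points map as p %*% t(R) + t.

rigid_identity <- function() list(R = diag(3), t = c(0, 0, 0))

#' Apply a rigid transform to points
#' @param tf list with rotation `R` and translation `t`.
#' @param pts n x 3 matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_rigid <- function(tf, pts) {
  sweep(matrix(pts, ncol = 3) %*% t(tf$R), 2, tf$t, "+")
}

compose_rigid <- function(a, b) {
  # (a o b)(p) = a(b(p))
  list(R = a$R %*% b$R, t = as.numeric(a$R %*% b$t) + a$t)
}

invert_rigid <- function(tf) {
  Rt <- t(tf$R)
  list(R = Rt, t = as.numeric(-Rt %*% tf$t))
}

rotation_from_axis_angle <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  k <- w / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

rotation_angle <- function(R) {
  acos(pmin(pmax((sum(diag(R)) - 1) / 2, -1), 1))
}

#' Least-squares rigid alignment of paired points (Kabsch)
#'
#' Finds rotation and translation minimizing the sum of squared distances
#' between `apply_rigid(tf, x)` and `y`, optionally weighted.
#'
#' @param x,y n x 3 matrices of corresponding points.
#' @param weights optional nonnegative weights.
#' @return rigid transform list (`R`, `t`).
#' @export
kabsch_rigid <- function(x, y, weights = NULL) {
  x <- matrix(x, ncol = 3); y <- matrix(y, ncol = 3)
  if (is.null(weights)) weights <- rep(1, nrow(x))
  w <- weights / sum(weights)
  cx <- colSums(x * w); cy <- colSums(y * w)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  H <- t(xc * w) %*% yc
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = as.numeric(cy - R %*% cx))
}
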