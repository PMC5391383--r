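# Internal vector geometry shared by the backbone builder, superposition and
# reach/contact calculations. All functions operate on n x 3 matrices so that
# per-frame quantities can be computed for every frame at once.

row_norm <- function(m) sqrt(rowSums(m * m))

row_unit <- function(m) m / row_norm(m)

row_cross <- function(a, b) {
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

#' @noRd
#' Natural-extension (NeRF) placement of the next atom in internal
#' coordinates, vectorised across frames: `a`, `b`, `c` are n x 3 positions of
#' the three preceding atoms, `r` the bond length c-d (Angstrom), `theta` the
#' bond angle b-c-d (degrees) and `chi` the torsion a-b-c-d (degrees, scalar
#' or length n).
place_atom <- function(a, b, c, r, theta, chi) {
  theta <- theta * pi / 180
  chi <- chi * pi / 180
  b2 <- row_unit(c - b)
  n <- row_unit(row_cross(b - a, b2))
  m <- row_cross(n, b2)
  d <- cbind(-r * cos(theta), r * sin(theta) * cos(chi), r * sin(theta) * sin(chi))
  c + d[, 1] * b2 + d[, 2] * m + d[, 3] * n
}

#' @noRd
#' Dihedral angle a-b-c-d in degrees, rows paired across the four matrices.
dihedral <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- row_cross(b1, b2)
  n2 <- row_cross(b2, b3)
  m1 <- row_cross(n1, row_unit(b2))
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  atan2(y, x) * 180 / pi
}

#' @noRd
#' Optimal rigid-body superposition (rotation + translation, no reflection)
#' of point set `p` onto `q` by SVD; returns the rotation matrix, the two
#' centroids, and the post-fit RMSD.
kabsch_fit <- function(p, q) {
  stopifnot(nrow(p) == nrow(q), ncol(p) == 3, ncol(q) == 3)
  cp <- colMeans(p)
  cq <- colMeans(q)
  p0 <- sweep(p, 2, cp)
  q0 <- sweep(q, 2, cq)
  s <- svd(crossprod(p0, q0))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- p0 %*% t(rot)
  list(
    rotation = rot, center_p = cp, center_q = cq,
    rmsd = sqrt(mean(rowSums((fitted - q0)^2)))
  )
}

#' @noRd
#' Apply the rigid transform from kabsch_fit to arbitrary coordinates.
apply_fit <- function(coords, fit) {
  sweep(sweep(coords, 2, fit$center_p) %*% t(fit$rotation), 2, fit$center_q, `+`)
}
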