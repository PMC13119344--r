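#' Pseudo bond angle over three points
#'
#' The virtual bond angle at `p2`: arccos of the normalized dot product of
#' `p1 - p2` and `p3 - p2`. Used on consecutive C-alpha atoms to describe
#' loop stem geometry (the tau descriptor).
#'
#' @param p1,p2,p3 Numeric length-3 coordinates (Angstrom).
#' @return Angle in degrees, in `[0, 180]`.
#' @export
pseudo_bond_angle <- function(p1, p2, p3) {
  v1 <- as.numeric(p1) - as.numeric(p2)
  v2 <- as.numeric(p3) - as.numeric(p2)
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-12 || n2 < 1e-12) {
    rlang::abort("coincident points: zero-length vector in bond angle")
  }
  ct <- sum(v1 * v2) / (n1 * n2)
  ct <- min(1, max(-1, ct))
  acos(ct) * 180 / pi
}

#' Signed pseudo torsion over four points
#'
#' The virtual torsion (dihedral) angle of the `p2`-`p3` axis, measured from
#' the `p1`-`p2`-`p3` plane to the `p2`-`p3`-`p4` plane, with the standard
#' right-handed sign convention. Used on consecutive C-alpha atoms (the alpha
#' descriptor) and for the disulphide chi3 dihedral.
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinates.
#' @param degrees Return degrees (default) or radians.
#' @return Signed angle in `(-180, 180]` degrees (or `(-pi, pi]` radians).
#' @export
pseudo_torsion <- function(p1, p2, p3, p4, degrees = TRUE) {
  b1 <- as.numeric(p2) - as.numeric(p1)
  b2 <- as.numeric(p3) - as.numeric(p2)
  b3 <- as.numeric(p4) - as.numeric(p3)
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20) {
    rlang::abort("degenerate dihedral: three consecutive points are collinear")
  }
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x)
  if (ang <= -pi) ang <- ang + 2 * pi
  if (degrees) ang * 180 / pi else ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Wrap an angle to (-pi, pi]
#'
#' @param x Angle(s) in radians.
#' @return Equivalent angle(s) in `(-pi, pi]`.
#' @export
wrap_angle <- function(x) {
  y <- x - 2 * pi * floor((x + pi) / (2 * pi))
  y[y <= -pi] <- y[y <= -pi] + 2 * pi
  y
}

# place a point from three reference points by internal coordinates:
# |d - c| = bond, angle(b, c, d) = angle (rad), torsion(a, b, c, d) = tors (rad)
place_internal <- function(a, b, c, bond, angle, tors) {
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  n <- cross3(b - a, bc)
  if (sum(n^2) < 1e-20) rlang::abort("degenerate internal-coordinate frame")
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d2 <- c(-bond * cos(angle),
          bond * sin(angle) * cos(tors),
          -bond * sin(angle) * sin(tors))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# random proper rotation matrix (uniform via QR of Gaussian matrix)
random_rotation <- function() {
  q <- qr(matrix(stats::rnorm(9), 3, 3))
  r <- qr.Q(q) %*% diag(sign(diag(qr.R(q))))
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

# apply rigid transform to the xyz columns of an atom table
transform_atoms <- function(atoms, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(rotation)
  atoms$x <- xyz[, 1] + translation[1]
  atoms$y <- xyz[, 2] + translation[2]
  atoms$z <- xyz[, 3] + translation[3]
  atoms
}
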