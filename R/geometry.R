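## Low-level 3D geometry used by every other module. All angles in degrees,
## torsions wrapped to (-180, 180], positions in Angstrom.

DEG <- 180 / pi

#' Wrap an angle in degrees to (-180, 180]
#' @param x numeric vector of angles, degrees.
#' @return wrapped angles; -180 maps to +180.
#' @export
wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

#' Wrap an angle in degrees to [0, 360)
#' @param x numeric vector of angles, degrees.
#' @export
wrap360 <- function(x) x %% 360

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

rowcross <- function(A, B) {
  cbind(A[, 2] * B[, 3] - A[, 3] * B[, 2],
        A[, 3] * B[, 1] - A[, 1] * B[, 3],
        A[, 1] * B[, 2] - A[, 2] * B[, 1])
}

rowdot <- function(A, B) rowSums(A * B)

vnorm <- function(a) sqrt(sum(a * a))

unit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("degenerate geometry: zero-length vector")
  a / n
}

#' Torsion (dihedral) angle of four points
#'
#' IUPAC sign convention: looking from p2 towards p3, positive angles are a
#' clockwise rotation of p4 relative to p1. Computed with the atan2
#' formulation, stable near +/-180 degrees.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors, Angstrom.
#' @return angle in degrees in (-180, 180].
#' @export
dihedral <- function(p1, p2, p3, p4) {
  unname(drop(dihedral_rows(rbind(p1), rbind(p2), rbind(p3), rbind(p4))))
}

## Vectorized dihedral over matrices of row-points.
dihedral_rows <- function(P1, P2, P3, P4) {
  b1 <- P2 - P1
  b2 <- P3 - P2
  b3 <- P4 - P3
  n2 <- sqrt(rowdot(b2, b2))
  if (any(rowdot(b1, b1) < 1e-16) || any(n2 * n2 < 1e-16) ||
      any(rowdot(b3, b3) < 1e-16)) {
    stop("degenerate geometry: coincident consecutive points in dihedral")
  }
  c12 <- rowcross(b1, b2)
  c23 <- rowcross(b2, b3)
  y <- rowdot(b1, c23) * n2
  x <- rowdot(c12, c23)
  wrap180(atan2(y, x) * DEG)
}

#' Bond angle at p2 formed by p1-p2-p3
#' @param p1,p2,p3 numeric 3-vectors.
#' @return angle in degrees in [0, 180].
#' @export
bond_angle <- function(p1, p2, p3) {
  u <- unit(p1 - p2)
  v <- unit(p3 - p2)
  acos(max(-1, min(1, sum(u * v)))) * DEG
}

#' Place a fourth atom from internal coordinates (NeRF)
#'
#' Returns the position `d` bonded to `c` with bond length `bond`, angle
#' b-c-d equal to `angle` and torsion a-b-c-d equal to `torsion`, using the
#' same sign convention as [dihedral()].
#'
#' @param a,b,c numeric 3-vectors of the three reference atoms.
#' @param bond bond length c-d, Angstrom.
#' @param angle bond angle b-c-d, degrees.
#' @param torsion torsion a-b-c-d, degrees.
#' @return numeric 3-vector.
#' @export
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle / DEG
  tor <- torsion / DEG
  bc <- unit(c - b)
  ab <- b - a
  n <- unit(vcross(ab, bc))
  m <- vcross(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + cbind(bc, m, n) %*% d2
}

## Rotation matrices about coordinate axes, angle in degrees.
rot_z <- function(theta) {
  t <- theta / DEG
  matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
}

rot_x <- function(theta) {
  t <- theta / DEG
  matrix(c(1, 0, 0, 0, cos(t), sin(t), 0, -sin(t), cos(t)), 3, 3)
}

## Rotation taking unit vector `from` onto unit vector `to` (Rodrigues).
rot_between <- function(from, to) {
  f <- unit(from); t2 <- unit(to)
  v <- vcross(f, t2)
  s <- vnorm(v)
  cth <- sum(f * t2)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    ## antiparallel: rotate 180 about any perpendicular axis
    p <- if (abs(f[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- unit(vcross(f, p))
    K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                  axis[2], -axis[1], 0), 3, 3)
    return(diag(3) + 2 * K %*% K)
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K * ((1 - cth) / (s * s))
}

## Apply rigid transform (R, t) to an n x 3 coordinate matrix.
xform <- function(xyz, R, t = c(0, 0, 0)) {
  sweep(xyz %*% t(R), 2, -t)
}
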