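## Vector geometry: signed dihedrals, internal-coordinate atom placement
## (NeRF), and the canonical residue-local frame.

#' Signed dihedral angle of four points
#'
#' IUPAC convention: looking from \code{p2} towards \code{p3}, a clockwise
#' rotation of the far bond relative to the near bond is positive. The
#' result lies in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstrom)
#' @return dihedral angle in degrees
#' @export
computeDihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10)
    stop("undefined dihedral: three of the points are collinear")
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## Vectorized NeRF: place atom D bonded to C given reference atoms A, B, C,
## bond length d (C-D), angle theta (B-C-D, degrees) and torsion tau
## (A-B-C-D, degrees). a, b, cc are n x 3 matrices; d/theta/tau scalars or
## length-n. Returns n x 3 matrix.
nerfPlace <- function(a, b, cc, d, theta, tau) {
  th <- theta * pi / 180
  ta <- -tau * pi / 180   # sign fixed so computeDihedral(A,B,C,D) == tau
  bc <- cc - b
  bcn <- bc / sqrt(rowSums(bc^2))
  ab <- b - a
  n <- rowCross(ab, bcn)
  n <- n / sqrt(rowSums(n^2))
  m <- rowCross(n, bcn)
  d2 <- cbind(-d * cos(th), d * sin(th) * cos(ta), d * sin(th) * sin(ta))
  cc + d2[, 1] * bcn + d2[, 2] * m + d2[, 3] * n
}

rowCross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Residue-local orthonormal frame
#'
#' Origin at CA; x axis towards N; z = unit(x cross (C - CA)); y = z cross x.
#' All precomputed rotamer grids live in this frame.
#'
#' @param n,ca,c numeric 3-vectors: backbone N, CA, C positions
#' @return list with \code{origin} (3-vector) and \code{rot} (3x3 matrix
#'   whose rows are the local axes); use with \link{toLocal}/\link{toGlobal}
#' @export
localFrame <- function(n, ca, c) {
  x <- n - ca
  x <- x / sqrt(sum(x^2))
  z <- cross3(x, c - ca)
  nz <- sqrt(sum(z^2))
  if (nz < 1e-8) stop("degenerate local frame: N, CA, C collinear")
  z <- z / nz
  y <- cross3(z, x)
  list(origin = ca, rot = rbind(x, y, z, deparse.level = 0))
}

#' Map global coordinates into a residue-local frame
#' @param frame a frame from \link{localFrame}
#' @param xyz n x 3 matrix (or 3-vector) of global coordinates
#' @return coordinates in the local frame, same shape
#' @export
toLocal <- function(frame, xyz) {
  xyz <- rbind3(xyz)
  sweep(xyz, 2, frame$origin) %*% t(frame$rot)
}

#' Map local-frame coordinates back to global coordinates
#' @inheritParams toLocal
#' @return global coordinates
#' @export
toGlobal <- function(frame, xyz) {
  xyz <- rbind3(xyz)
  sweep(xyz %*% frame$rot, 2, -frame$origin)
}

rbind3 <- function(xyz) {
  if (is.null(dim(xyz))) matrix(xyz, ncol = 3) else as.matrix(xyz)
}
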