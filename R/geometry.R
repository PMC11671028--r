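# Internal 3D geometry helpers. All angles in degrees at the API surface,
# radians internally. Coordinates are plain numeric length-3 vectors or
# n x 3 matrices in Angstrom.

.deg2rad <- pi / 180
.rad2deg <- 180 / pi

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

## angle a-b-c at vertex b, degrees
angleDeg <- function(a, b, c) {
  u <- a - b
  v <- c - b
  ct <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(pmin(1, pmax(-1, ct))) * .rad2deg
}

## signed dihedral p1-p2-p3-p4, degrees, IUPAC sign convention
dihedralDeg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / vnorm(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * .rad2deg
}

## Natural extension of reference frame: place atom D given positions of
## A (dihedral reference), B (angle reference), C (bonded atom) so that
## |D-C| = bond, angle(B,C,D) = ang and dihedral(A,B,C,D) = dih.
placeAtom <- function(A, B, C, bond, ang, dih) {
  theta <- ang * .deg2rad
  phi <- -dih * .deg2rad  # sign matches dihedralDeg(A, B, C, placed)
  u2 <- unitv(C - B)
  n <- unitv(cross3(B - A, C - B))
  m <- cross3(n, u2)
  C + bond * (-cos(theta) * u2 + sin(theta) * (cos(phi) * m + sin(phi) * n))
}

## Rotation matrix for rotation by `ang` degrees about unit axis (Rodrigues)
rotationMatrix <- function(axis, ang) {
  a <- unitv(axis)
  th <- ang * .deg2rad
  K <- matrix(c(0, a[3L], -a[2L],
                -a[3L], 0, a[1L],
                a[2L], -a[1L], 0), 3L, 3L)
  diag(3L) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

## any unit vector perpendicular to u (deterministic)
perpVector <- function(u) {
  u <- unitv(u)
  ref <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unitv(cross3(u, ref))
}

## Deterministic generalized-spiral (golden-angle) point set on the unit sphere
goldenSpiralPoints <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

## squared distances between one point and the rows of a matrix
distSqTo <- function(p, m) {
  (m[, 1L] - p[1L])^2 + (m[, 2L] - p[2L])^2 + (m[, 3L] - p[3L])^2
}

## full pairwise distance matrix between rows of a and rows of b
crossDist <- function(a, b) {
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * (a %*% t(b))
  sqrt(pmax(d2, 0))
}
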