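## Internal vector geometry used by the detectors. Coordinates are plain
## n x 3 matrices in Angstrom.

vnorm <- function(v) sqrt(sum(v * v))

unit_vec <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("zero-length vector has no direction")
  v / n
}

## Angle a-b-c at vertex b, degrees in [0, 180].
angle_deg <- function(a, b, c) {
  u <- a - b
  v <- c - b
  nu <- vnorm(u); nv <- vnorm(v)
  if (nu == 0 || nv == 0) return(NA_real_)
  cosang <- sum(u * v) / (nu * nv)
  cosang <- max(-1, min(1, cosang))
  acos(cosang) * 180 / pi
}

dist3 <- function(a, b) vnorm(a - b)

## Centroid and (unit) normal of a planar-ish ring given its coordinates.
## Normal is the singular direction of least variance; sign is arbitrary.
ring_centroid_normal <- function(xyz) {
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  list(centroid = ctr, normal = sv$v[, 3])
}

## Minimal pairwise distance between two coordinate sets.
min_cross_dist <- function(xa, xb) {
  ## fast enough for the small groups seen here
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  sqrt(max(0, min(d2)))
}

## Rotation matrix about unit axis by angle (degrees); Rodrigues form.
rotation_about <- function(axis, theta_deg) {
  u <- unit_vec(axis)
  th <- theta_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

## An arbitrary unit vector perpendicular to u.
perp_vec <- function(u) {
  u <- unit_vec(u)
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit_vec(ref - sum(ref * u) * u)
}
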