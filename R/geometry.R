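## Small 3D geometry helpers shared by the structural modules.

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## Angle at vertex b of the path a-b-c, in degrees.
vangle <- function(a, b, c) {
  u <- vunit(a - b); w <- vunit(c - b)
  acos(max(-1, min(1, sum(u * w)))) * 180 / pi
}

## All pairwise Euclidean distances between the rows of two n x 3 matrices.
cross_dist <- function(xyz_a, xyz_b) {
  a2 <- rowSums(xyz_a^2)
  b2 <- rowSums(xyz_b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(xyz_a, xyz_b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

## Deterministic quasi-uniform points on the unit sphere (golden-spiral
## lattice). Used by the surface-area integrator.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

## Optimal least-squares superposition (Kabsch, via SVD) of `mobile` onto
## `fixed`; both are n x 3 with row correspondence. Returns the transformed
## mobile coordinates and the RMSD.
kabsch_superpose <- function(mobile, fixed) {
  stopifnot(nrow(mobile) == nrow(fixed), nrow(mobile) >= 3)
  cm <- colMeans(mobile); cf <- colMeans(fixed)
  a <- sweep(mobile, 2, cm); b <- sweep(fixed, 2, cf)
  s <- svd(crossprod(a, b))
  d <- sign(det(tcrossprod(s$v, s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  moved <- sweep(a %*% t(rot), 2, cf, "+")
  rmsd <- sqrt(mean(rowSums((moved - fixed)^2)))
  list(xyz = moved, rmsd = rmsd, rotation = rot)
}

## Axis-angle rotation matrix (axis need not be unit length; angle in degrees).
rotation_matrix <- function(axis, angle_deg) {
  u <- vunit(axis)
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct),      ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),      uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}
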