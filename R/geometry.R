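# Small 3-D geometry toolkit shared by the builders and validators.
# All angles are in degrees at the API surface; radians internally.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Bond angle a-b-c in degrees
#' @noRd
angle3 <- function(a, b, c) {
  u <- unitv(a - b); v <- unitv(c - b)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

#' Signed torsion angle a-b-c-d in degrees, IUPAC sign convention
#' @noRd
torsion4 <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unitv(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  rad2deg(atan2(y, x))
}

# NeRF atom placement: position the fourth atom given three reference
# positions, a bond length, a bond angle (to c) and a torsion (a-b-c-new).
place_atom <- function(a, b, c, bond, angle, torsion) {
  angle <- deg2rad(angle); torsion <- deg2rad(torsion)
  bc <- unitv(c - b)
  n <- unitv(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- c(-bond * cos(angle),
          bond * sin(angle) * cos(torsion),
          bond * sin(angle) * sin(torsion))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Rotation matrix for a right-handed rotation of `theta` degrees about `axis`.
rotmat_axis <- function(axis, theta) {
  u <- unitv(axis)
  th <- deg2rad(theta)
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct),      ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),      uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}

# Pairwise squared distances between two coordinate matrices (n x 3, m x 3).
cross_dist2 <- function(xyz1, xyz2) {
  s1 <- rowSums(xyz1^2)
  s2 <- rowSums(xyz2^2)
  d2 <- outer(s1, s2, "+") - 2 * tcrossprod(xyz1, xyz2)
  d2[d2 < 0] <- 0
  d2
}

min_cross_dist <- function(xyz1, xyz2) {
  if (nrow(xyz1) == 0L || nrow(xyz2) == 0L) return(Inf)
  sqrt(min(cross_dist2(xyz1, xyz2)))
}
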