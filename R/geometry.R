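# Small 3-D geometry kernel used by scaffold building, rotamer placement and
# local-frame contact statistics. All coordinates are plain numeric vectors
# or n x 3 matrices in Angstrom.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Dihedral angle defined by four points
#'
#' @param p1,p2,p3,p4 numeric 3-vectors.
#' @return Angle in degrees in (-180, 180].
#' @keywords internal
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  rad2deg(atan2(y, x))
}

bond_angle <- function(p1, p2, p3) {
  v1 <- unitv(p1 - p2)
  v2 <- unitv(p3 - p2)
  rad2deg(acos(max(-1, min(1, sum(v1 * v2)))))
}

# NeRF (natural extension reference frame) placement: position atom D given
# predecessors A-B-C, the C-D bond length, the B-C-D angle and the
# A-B-C-D torsion (degrees).
place_atom <- function(a, b, c, length, angle, torsion) {
  ang <- deg2rad(angle)
  tor <- deg2rad(torsion)
  bc <- unitv(c - b)
  n <- unitv(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- c(-length * cos(ang),
          length * sin(ang) * cos(tor),
          -length * sin(ang) * sin(tor))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

# Orthonormal local frame from three points (N, CA, C style): origin at ca,
# x along n->c direction projected conventions kept fixed and documented.
# Returns list(origin, R) with R a 3x3 rotation whose rows are the axes;
# world -> local: R %*% (p - origin); local -> world: t(R) %*% p + origin.
local_frame <- function(n, ca, c) {
  e1 <- unitv(c - n)
  u <- ca - n
  e3 <- unitv(vcross(e1, u))
  e2 <- vcross(e3, e1)
  list(origin = ca, R = rbind(e1, e2, e3, deparse.level = 0))
}

to_local <- function(frame, xyz) {
  xyz <- matrix(xyz, ncol = 3L)
  t(frame$R %*% (t(xyz) - frame$origin))
}

to_world <- function(frame, xyz) {
  xyz <- matrix(xyz, ncol = 3L)
  t(crossprod(frame$R, t(xyz)) + frame$origin)
}

# Random rigid rotation matrix (uniform via QR of Gaussian), used by fixtures
# and invariance tests.
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9L), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}
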