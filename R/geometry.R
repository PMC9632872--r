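#' Signed torsion angle of four points
#'
#' Computes the IUPAC signed dihedral defined by four points, in degrees in
#' (-180, 180]. The sign is positive for a clockwise rotation of the far bond
#' when sighting down the central bond (p2 -> p3), the convention used for
#' protein backbone and side-chain torsions.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (coordinates in Angstrom).
#' @return Signed angle in degrees in (-180, 180].
#' @examples
#' torsion_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))   # cis, 0
#' torsion_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))  # trans, 180
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  nb2 <- sqrt(sum(b2^2))
  if (sqrt(sum(b1^2)) < 1e-9 || nb2 < 1e-9 || sqrt(sum(b3^2)) < 1e-9)
    stop("degenerate geometry: coincident consecutive points")
  u2 <- b2 / nb2
  # project the two outer half-plane vectors (p1 - p2, p4 - p3) onto the
  # plane normal to the central bond
  v <- -b1 - sum(-b1 * u2) * u2
  w <- b3 - sum(b3 * u2) * u2
  if (sqrt(sum(v^2)) < 1e-9 || sqrt(sum(w^2)) < 1e-9)
    stop("degenerate geometry: collinear consecutive points")
  x <- sum(v * w)
  y <- sum(crossprod3(v, w) * u2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# cross product of two 3-vectors
crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(v) sqrt(sum(v^2))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a near-zero vector")
  v / n
}

#' Place an atom from internal coordinates
#'
#' Natural-extension (Z-matrix) placement: given three previously placed
#' atoms a, b, c, returns the position d at bond length `r` from c, bond
#' angle `theta` (b-c-d) and torsion `chi` (a-b-c-d). The realized torsion
#' measured with [torsion_angle()] equals `chi` exactly (to rounding), which
#' makes this the single geometric primitive behind all fixture builders.
#'
#' @param a,b,c Numeric 3-vectors, already-placed atoms.
#' @param r Bond length c-d in Angstrom.
#' @param theta Bond angle b-c-d in degrees, in (0, 180).
#' @param chi Torsion a-b-c-d in degrees.
#' @return Numeric 3-vector, the position of d.
#' @export
place_atom <- function(a, b, c, r, theta, chi) {
  if (r <= 0) stop("bond length must be positive")
  if (theta <= 0 || theta >= 180) stop("bond angle must be in (0, 180)")
  th <- theta * pi / 180
  ch <- chi * pi / 180
  bc <- unitv(c - b)
  n <- unitv(crossprod3(b - a, bc))
  m <- crossprod3(n, bc)
  d2 <- c(-r * cos(th), r * sin(th) * cos(ch), r * sin(th) * sin(ch))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# rotation matrix taking unit vector u onto unit vector v (Rodrigues)
rotation_between <- function(u, v) {
  u <- unitv(u); v <- unitv(v)
  w <- crossprod3(u, v)
  s <- vnorm(w)
  cth <- sum(u * v)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # opposite vectors: rotate 180 deg about any perpendicular axis
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- unitv(crossprod3(u, p))
    K <- skew3(axis)
    return(diag(3) + 2 * K %*% K)
  }
  K <- skew3(w / s)
  diag(3) + s * K + (1 - cth) * (K %*% K)
}

skew3 <- function(a) {
  matrix(c(0, a[3], -a[2],
           -a[3], 0, a[1],
           a[2], -a[1], 0), 3, 3)
}
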