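# Low-level vector geometry shared across the package. All angles are in
# degrees at the API surface; radians are used only inside formulas.

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(a) sqrt(sum(a * a))

vunit <- function(a) {
  n <- vnorm(a)
  if (!is.finite(n) || n < 1e-10) {
    stop("cannot normalize a (near-)zero-length vector")
  }
  a / n
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap an angle in degrees into (-180, 180]
#' @param x numeric vector of angles in degrees.
#' @return wrapped angles.
#' @keywords internal
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

#' Torsion angle defined by four points
#'
#' Standard IUPAC-signed dihedral: looking down the p2->p3 bond, a clockwise
#' rotation from p1 to p4 is positive.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstroms).
#' @return angle in degrees in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-8 || vnorm(n2) < 1e-8) {
    stop("torsion undefined: three consecutive points are (near-)collinear")
  }
  y <- sum(vcross(n1, n2) * (b2 / vnorm(b2)))
  wrap_angle(rad2deg(atan2(y, sum(n1 * n2))))
}

#' Torsion angle defined by three direction vectors
#'
#' The dihedral about the middle vector b2, between the plane spanned by
#' (b1, b2) and the plane spanned by (b2, b3). This is the four-point
#' torsion of the polyline p, p + b1, p + b1 + b2, p + b1 + b2 + b3.
#'
#' @param b1,b2,b3 numeric 3-vectors.
#' @return angle in degrees in (-180, 180].
#' @export
vector_dihedral <- function(b1, b2, b3) {
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10) {
    stop("torsion undefined for (near-)parallel vectors")
  }
  y <- sum(vcross(n1, n2) * (b2 / vnorm(b2)))
  wrap_angle(rad2deg(atan2(y, sum(n1 * n2))))
}

#' Angle between two vectors in degrees
#' @keywords internal
vector_angle <- function(a, b) {
  ca <- sum(vunit(a) * vunit(b))
  rad2deg(acos(max(-1, min(1, ca))))
}

# Place atom D given three predecessors A, B, C, the C-D bond length, the
# B-C-D bond angle and the A-B-C-D torsion (NeRF internal-to-Cartesian step).
place_atom <- function(a, b, c3, bond, angle_deg, torsion_deg) {
  bc <- vunit(c3 - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  ang <- deg2rad(angle_deg)
  tor <- deg2rad(torsion_deg)
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
  c3 + d[1L] * bc + d[2L] * m + d[3L] * n
}
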