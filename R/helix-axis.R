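# Helix-axis estimation from Calpha coordinates.
#
# Local-axis construction: at each interior Calpha the bisector of the
# two bonds to its neighbours points toward the helix axis; the cross
# product of two successive bisectors is parallel to the axis. Averaging
# over the window and fitting the circle centre in the orthogonal plane
# gives a line (anchor + unit direction) that is exact for an ideal
# helix and robust to moderate dihedral noise.

# Algebraic (Kasa) circle fit; pts is m x 2, returns the centre.
circle_fit_center <- function(pts) {
  A <- cbind(2 * pts[, 1L], 2 * pts[, 2L], 1)
  b <- rowSums(pts^2)
  sol <- qr.solve(A, b)
  sol[1:2]
}

#' Fit a helix axis to a window of Calpha atoms
#'
#' @param ca m x 3 matrix of consecutive Calpha coordinates, or a
#'   `backbone_chain`.
#' @param window optional integer residue indices (consecutive) to use;
#'   default: all rows. At least 4 Calpha atoms are required.
#' @return list with `anchor` (a point on the axis at the window's
#'   axial midpoint), `direction` (unit vector pointing from the
#'   N-side toward the C-side of the window), and `radius` (mean
#'   distance of the Calpha atoms from the axis).
#' @export
helix_axis <- function(ca, window = NULL) {
  if (inherits(ca, "backbone_chain")) ca <- ca$CA
  ca <- as.matrix(ca)
  if (!is.null(window)) {
    if (any(diff(as.integer(window)) != 1L)) stop("window must be consecutive")
    ca <- ca[window, , drop = FALSE]
  }
  m <- nrow(ca)
  if (m < 4L) stop("helix axis needs >= 4 consecutive Calpha atoms")
  bis <- matrix(0, m - 2L, 3L)
  for (i in 2:(m - 1L)) {
    bis[i - 1L, ] <- vunit(vunit(ca[i - 1L, ] - ca[i, ]) + vunit(ca[i + 1L, ] - ca[i, ]))
  }
  span <- ca[m, ] - ca[1L, ]
  dirs <- matrix(0, m - 3L, 3L)
  for (i in seq_len(m - 3L)) {
    ax <- vcross(bis[i, ], bis[i + 1L, ])
    if (vnorm(ax) < 1e-8) stop("degenerate (collinear) Calpha window")
    ax <- vunit(ax)
    if (sum(ax * span) < 0) ax <- -ax
    dirs[i, ] <- ax
  }
  direction <- vunit(colMeans(dirs))
  # orthonormal basis of the plane normal to the axis
  ref <- if (abs(direction[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- vunit(vcross(direction, ref))
  e2 <- vcross(direction, e1)
  proj <- cbind(ca %*% e1, ca %*% e2)
  ctr2 <- circle_fit_center(proj)
  axial <- as.vector(ca %*% direction)
  anchor <- ctr2[1L] * e1 + ctr2[2L] * e2 + mean(axial) * direction
  radius <- mean(sqrt((proj[, 1L] - ctr2[1L])^2 + (proj[, 2L] - ctr2[2L])^2))
  list(anchor = as.vector(anchor), direction = as.vector(direction),
       radius = radius)
}

#' Residues per turn of a helical Calpha trace
#'
#' Fits the helix axis, then unwraps the angular position of each
#' Calpha about that axis and reports 360 degrees divided by the mean
#' per-residue angular advance.
#'
#' @param ca m x 3 Calpha matrix or a `backbone_chain` (m >= 5).
#' @return residues per full turn (positive number).
#' @export
residues_per_turn <- function(ca) {
  if (inherits(ca, "backbone_chain")) ca <- ca$CA
  ca <- as.matrix(ca)
  if (nrow(ca) < 5L) stop("need >= 5 residues")
  ax <- helix_axis(ca)
  ref <- if (abs(ax$direction[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- vunit(vcross(ax$direction, ref))
  e2 <- vcross(ax$direction, e1)
  rel <- sweep(ca, 2, ax$anchor)
  th <- atan2(as.vector(rel %*% e2), as.vector(rel %*% e1))
  dth <- diff(th)
  dth <- (dth + pi) %% (2 * pi) - pi  # unwrap per-residue steps
  360 / abs(mean(rad2deg(dth)))
}
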