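#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation R and translation t minimizing the RMSD of
#' P %*% t(R) + t against Q. Reflections are excluded, so enantiomers
#' cannot be superposed exactly.
#'
#' @param P,Q m x 3 matrices of paired points (m >= 3, not all
#'   collinear); P is moved onto Q.
#' @return list with `rotation` (3 x 3, det +1), `translation`
#'   (length-3), `rmsd` (Angstroms), and `transformed` (P after the
#'   fit).
#' @export
kabsch_superpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q))) stop("point sets must have identical dimensions")
  m <- nrow(P)
  if (m < 3L || ncol(P) != 3L) stop("need >= 3 paired 3-D points")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  moved <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Qc)^2)))
  tr <- cq - as.vector(R %*% cp)
  list(rotation = R, translation = tr, rmsd = rmsd,
       transformed = sweep(moved, 2, cq, "+"))
}

#' Apply a rigid transform to a coordinate matrix
#' @param X m x 3 matrix.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 vector.
#' @return transformed m x 3 matrix.
#' @export
apply_transform <- function(X, rotation, translation) {
  sweep(as.matrix(X) %*% t(rotation), 2, translation, "+")
}

#' Random proper rotation matrix (for property tests and grid searches)
#' @param angles optional c(a, b, c) Euler-like angles in radians; random
#'   when omitted (uses the session RNG).
#' @return 3 x 3 rotation matrix with det +1.
#' @export
rotation_matrix <- function(angles = NULL) {
  if (is.null(angles)) angles <- c(stats::runif(1, 0, 2 * pi),
                                   acos(stats::runif(1, -1, 1)),
                                   stats::runif(1, 0, 2 * pi))
  a <- angles[1L]; b <- angles[2L]; g <- angles[3L]
  Rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE)
  Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, byrow = TRUE)
  Rz2 <- matrix(c(cos(g), -sin(g), 0, sin(g), cos(g), 0, 0, 0, 1), 3, byrow = TRUE)
  Rz1 %*% Ry %*% Rz2
}
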