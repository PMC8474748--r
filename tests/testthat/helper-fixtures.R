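# Shared fixture builders for the test suite. Everything is generated
# in code; no binary fixtures.

ideal_helix_df <- function(n) {
  d <- as.data.frame(as.list(ideal_helix_dihedrals()))
  d[rep(1L, n), , drop = FALSE]
}

# random dihedral table with angles away from degenerate values
random_dihedrals <- function(n) {
  data.frame(phi = runif(n, -170, 170),
             psi = runif(n, -170, 170),
             omega = sample(c(-1, 1), n, replace = TRUE) * runif(n, 150, 180))
}

# helix-loop-helix chain with explicit loop torsions
hlh_chain <- function(loop_phi, loop_psi, l1 = 14, l3 = 14) {
  nl <- length(loop_phi)
  n <- l1 + nl + l3
  d <- ideal_helix_df(n)
  idx <- (l1 + 1L):(l1 + nl)
  d$phi[idx] <- loop_phi
  d$psi[idx] <- loop_psi
  chain <- build_backbone(d)
  hlh_fragment(chain, 1:l1, idx, (l1 + nl + 1L):n)
}

# lightweight fragment stub carrying only a loop ABEGO string (for
# string-level filter logic)
loop_stub <- function(abego) {
  structure(list(id = abego, loop_abego = abego), class = "hlh_fragment")
}

# brute-force TM-score oracle: maximize the TM sum over rigid motions
# by multi-start quasi-Newton refinement from a rotation grid
tm_oracle <- function(model, reference, l_ref = nrow(reference)) {
  d0 <- tm_d0(l_ref)
  cm <- colMeans(model)
  cq <- colMeans(reference)
  P0 <- sweep(model, 2, cm)
  Q <- sweep(reference, 2, cq)
  score_of <- function(par) {
    R <- rot_from_angles(par[1:3])
    moved <- P0 %*% t(R)
    moved <- sweep(moved, 2, par[4:6], "+")
    d <- sqrt(rowSums((moved - Q)^2))
    sum(1 / (1 + (d / d0)^2)) / l_ref
  }
  n <- nrow(P0)
  h1 <- seq_len(floor(n / 2))
  h2 <- (floor(n / 2) + 1L):n
  best <- -Inf
  grid <- expand.grid(a = seq(0, 2 * pi, length.out = 5)[-5],
                      b = seq(0, pi, length.out = 4),
                      g = seq(0, 2 * pi, length.out = 5)[-5])
  for (k in seq_len(nrow(grid))) {
    ang <- as.numeric(grid[k, ])
    R <- rot_from_angles(ang)
    rotated <- P0 %*% t(R)
    # translation starts: centroid-aligned globally and per half, so
    # substructure fits are reachable
    t_starts <- list(c(0, 0, 0),
                     colMeans(Q[h1, , drop = FALSE]) -
                       colMeans(rotated[h1, , drop = FALSE]),
                     colMeans(Q[h2, , drop = FALSE]) -
                       colMeans(rotated[h2, , drop = FALSE]))
    for (t0 in t_starts) {
      o <- stats::optim(c(ang, t0), function(p) -score_of(p),
                        method = "Nelder-Mead",
                        control = list(maxit = 600, reltol = 1e-11))
      if (-o$value > best) best <- -o$value
    }
  }
  best
}

rot_from_angles <- function(ang) {
  a <- ang[1L]; b <- ang[2L]; g <- ang[3L]
  Rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE)
  Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, byrow = TRUE)
  Rz2 <- matrix(c(cos(g), -sin(g), 0, sin(g), cos(g), 0, 0, 0, 1), 3, byrow = TRUE)
  Rz1 %*% Ry %*% Rz2
}

wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

# local maxima of a numeric vector with NA gaps (edges count when they
# exceed their only available neighbour)
column_peaks <- function(v) {
  idx <- which(!is.na(v))
  p <- integer(0)
  for (j in seq_along(idx)) {
    lo <- if (j > 1L) v[idx[j - 1L]] else -Inf
    hi <- if (j < length(idx)) v[idx[j + 1L]] else -Inf
    if (v[idx[j]] > lo && v[idx[j]] > hi) p <- c(p, idx[j])
  }
  p
}
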