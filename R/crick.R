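# Parametric (Crick) generation of ideal helical bundles, used as the
# CW/CCW reference decoys for TM-score counting.
#
# Each chain is a minor helix (radius r1, ~3.6 residues/turn, rise d per
# residue along its local axis) wound about a superhelical axis of
# radius R and pitch P. The superhelical phase advances by
# w0 = d / sqrt(R^2 + (P/2pi)^2) per residue, so that arc length along
# the axis curve grows by d per residue; the pitch angle is
# alpha = atan(2*pi*R / P).

#' Crick parameter set for reference bundle generation
#'
#' Defaults are the settings used throughout: oligomeric state 3,
#' superhelical radius 9.0 A (scaled by the radius variant), pitch
#' 300 A, interface angle 20 degrees (entering as the minor-helix
#' phase of every chain), and standard minor-helix values (r1 = 2.26 A,
#' rise 1.51 A/residue, 3.62 residues per minor turn).
#'
#' @param oligomer_state number of chains.
#' @param superhelical_radius R in Angstroms.
#' @param pitch P in Angstroms (axial travel per superhelical turn).
#' @param interface_angle minor-helix phase offset phi1 in degrees.
#' @param minor_helix_radius r1 in Angstroms.
#' @param rise_per_residue d in Angstroms.
#' @param residues_per_minor_turn minor-helix periodicity.
#' @return named list of class `crick_params`.
#' @export
crick_params <- function(oligomer_state = 3, superhelical_radius = 9.0,
                         pitch = 300, interface_angle = 20,
                         minor_helix_radius = 2.26, rise_per_residue = 1.51,
                         residues_per_minor_turn = 3.62) {
  if (superhelical_radius <= 0) stop("superhelical radius must be positive")
  if (pitch <= 0) stop("pitch must be positive")
  if (oligomer_state < 2) stop("oligomer state must be >= 2")
  structure(list(oligomer_state = oligomer_state,
                 superhelical_radius = superhelical_radius, pitch = pitch,
                 interface_angle = interface_angle,
                 minor_helix_radius = minor_helix_radius,
                 rise_per_residue = rise_per_residue,
                 residues_per_minor_turn = residues_per_minor_turn),
            class = "crick_params")
}

# Calpha trace of one chain; t is the residue coordinate (may be
# fractional/centered), phi0 the superhelical phase of the chain.
crick_chain_ca <- function(params, t, phi0 = 0, straight = FALSE) {
  p <- params
  r1 <- p$minor_helix_radius
  d <- p$rise_per_residue
  w1 <- 2 * pi / p$residues_per_minor_turn
  phi1 <- deg2rad(p$interface_angle)
  if (straight) {
    w0 <- 0
    alpha <- 0
    z0 <- d * t
  } else {
    R <- p$superhelical_radius
    cP <- p$pitch / (2 * pi)
    w0 <- d / sqrt(R^2 + cP^2)
    alpha <- atan2(2 * pi * R, p$pitch)
    z0 <- cP * w0 * t
  }
  R <- p$superhelical_radius
  a0 <- w0 * t + phi0
  a1 <- w1 * t + phi1
  x <- R * cos(a0) + r1 * cos(a0) * cos(a1) - r1 * cos(alpha) * sin(a0) * sin(a1)
  y <- R * sin(a0) + r1 * sin(a0) * cos(a1) + r1 * cos(alpha) * cos(a0) * sin(a1)
  z <- z0 - r1 * sin(alpha) * sin(a1)
  cbind(x, y, z)
}

#' Generate an ideal coiled coil as Calpha traces
#'
#' All chains run parallel (N to C along +z) with superhelical phases
#' 2*pi*k/n; each chain is centered axially so chains of unequal length
#' share a common midplane.
#'
#' @param params a `crick_params` object.
#' @param helix_length residues per chain; either a single count or a
#'   vector with one length per chain.
#' @param n_chains number of chains (default: the oligomer state).
#' @param straight if TRUE, take the infinite-pitch limit (straight
#'   helix axes exactly parallel to z).
#' @return list of m x 3 Calpha matrices, one per chain.
#' @export
generate_coiled_coil <- function(params, helix_length,
                                 n_chains = params$oligomer_state,
                                 straight = FALSE) {
  if (!inherits(params, "crick_params")) stop("params must be crick_params")
  len <- rep_len(as.integer(helix_length), n_chains)
  if (any(len < 5L)) stop("helix length must be >= 5")
  lapply(seq_len(n_chains), function(k) {
    t <- seq(0, len[k] - 1L) - (len[k] - 1L) / 2
    crick_chain_ca(params, t, phi0 = 2 * pi * (k - 1L) / n_chains,
                   straight = straight)
  })
}

#' Re-sort a parallel trimer into a single up-down-up chain
#'
#' Reverses the residue order of the second chain (making its direction
#' "down") and concatenates the three chains in order 1 -> 2 -> 3.
#' Coordinates are untouched, so all inter-helix geometry is preserved;
#' applying the operation twice restores the original residue order.
#'
#' @param chains list of three Calpha matrices, or a `bundle_decoy`.
#' @return a `bundle_decoy` (Calpha-only) with fields `ca`,
#'   `helix_lengths`, `chirality` (measured), `variant`, `params`.
#' @export
to_updown <- function(chains) {
  if (inherits(chains, "bundle_decoy")) {
    chains <- split_decoy_helices(chains)
  }
  if (length(chains) != 3L) stop("expected three helices")
  chains[[2L]] <- chains[[2L]][rev(seq_len(nrow(chains[[2L]]))), , drop = FALSE]
  ca <- do.call(rbind, chains)
  dec <- structure(list(ca = ca, helix_lengths = vapply(chains, nrow, 1L),
                        chirality = NA_character_, variant = NA_real_,
                        params = NULL),
                   class = "bundle_decoy")
  dec$chirality <- classify_chirality(dec)
  dec
}

split_decoy_helices <- function(decoy) {
  ends <- cumsum(decoy$helix_lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_along(ends), function(k) decoy$ca[starts[k]:ends[k], , drop = FALSE])
}

#' Mirror a bundle decoy
#'
#' Negates the x coordinate of every atom and flips the chirality label
#' (CW <-> CCW). Chain order and residue order are preserved. The
#' operation is an involution.
#'
#' @param decoy a `bundle_decoy`.
#' @return the mirrored `bundle_decoy`.
#' @export
mirror_bundle <- function(decoy) {
  decoy$ca[, 1L] <- -decoy$ca[, 1L]
  decoy$chirality <- switch(decoy$chirality, CW = "CCW", CCW = "CW",
                            classify_chirality(decoy))
  decoy
}

#' Classify the CW/CCW arrangement of a three-helix bundle
#'
#' Helix centroids are projected onto the plane normal to the bundle
#' axis and the signed area of the triangle 1 -> 2 -> 3 is evaluated as
#' seen from the N-terminal end of helix 1 looking down the bundle:
#' clockwise order gives "CW", counter-clockwise "CCW". Mirroring always
#' flips the label.
#'
#' @param decoy a `bundle_decoy` (three helices).
#' @return "CW" or "CCW".
#' @export
classify_chirality <- function(decoy) {
  hel <- split_decoy_helices(decoy)
  if (length(hel) != 3L) stop("chirality defined for three-helix bundles")
  axes <- lapply(hel, helix_axis)
  u1 <- axes[[1L]]$direction
  # bundle axis: mean helix direction with the antiparallel middle helix
  # flipped into the common frame
  dirs <- t(vapply(axes, function(a) {
    if (sum(a$direction * u1) < 0) -a$direction else a$direction
  }, numeric(3)))
  v <- vunit(colMeans(dirs))
  cent <- t(vapply(hel, colMeans, numeric(3)))
  p <- sweep(cent, 2, cent[1L, ])
  s <- sum(vcross(p[2L, ], p[3L, ]) * v)
  if (abs(s) < 1e-9) stop("collinear helix centroids: chirality undefined")
  if (s > 0) "CW" else "CCW"
}

#' Build a CW or CCW up-down-up three-helix reference decoy
#'
#' Generates a parallel trimer from the Crick parameterization with the
#' base radius scaled by `variant`, re-sorts it to up-down-up chain
#' order, and mirrors it if needed to obtain the requested chirality.
#'
#' @param helix_lengths integer vector of three helix lengths
#'   (residues); a scalar is recycled.
#' @param chirality "CW" or "CCW".
#' @param variant radius scaling factor (1.00 gives the base 9.0 A
#'   radius; 0.75, 0.90, 1.10, 1.25 give 6.75, 8.1, 9.9, 11.25 A).
#' @param params base `crick_params` (the radius inside is multiplied
#'   by `variant`).
#' @return a `bundle_decoy`.
#' @export
make_reference_bundle <- function(helix_lengths, chirality = c("CW", "CCW"),
                                  variant = 1.0,
                                  params = crick_params()) {
  chirality <- match.arg(chirality)
  helix_lengths <- rep_len(as.integer(helix_lengths), 3L)
  p <- params
  p$superhelical_radius <- p$superhelical_radius * variant
  chains <- generate_coiled_coil(p, helix_lengths, n_chains = 3L)
  dec <- to_updown(chains)
  dec$variant <- variant
  dec$params <- p
  if (dec$chirality != chirality) dec <- mirror_bundle(dec)
  dec
}

#' @export
print.bundle_decoy <- function(x, ...) {
  cat(sprintf("<bundle_decoy: helices %s, %s, variant %s>\n",
              paste(x$helix_lengths, collapse = "/"), x$chirality,
              ifelse(is.na(x$variant), "?", format(x$variant))))
  invisible(x)
}

# Average out the minor helix with a boxcar window spanning exactly one
# minor-helix period (fractional end weights), leaving samples of the
# local helix-axis curve. Drops floor(period/2) samples at each end.
smooth_minor_helix <- function(ca, period = 3.62) {
  ca <- as.matrix(ca)
  half <- ceiling((period - 1) / 2)
  ks <- -half:half
  w <- pmax(0, pmin(ks + 0.5, period / 2) - pmax(ks - 0.5, -period / 2))
  w <- w / sum(w)
  m <- nrow(ca)
  if (m < length(ks) + 1L) stop("trace too short to average out the minor helix")
  idx <- (half + 1L):(m - half)
  out <- matrix(0, length(idx), 3L)
  for (j in seq_along(ks)) {
    out <- out + w[j] * ca[idx + ks[j], , drop = FALSE]
  }
  out
}

#' Measure the superhelical radius of a bundle decoy
#'
#' Each helix's Calpha trace is reduced to its local axis curve by
#' averaging out the minor helix; the global bundle axis is the line
#' through the centroid of all axis samples along the mean helix
#' direction (middle helix flipped). Returns the mean perpendicular
#' distance of the axis samples from that line.
#'
#' @param decoy a `bundle_decoy`.
#' @return radius in Angstroms.
#' @export
measure_radius <- function(decoy) {
  hel <- split_decoy_helices(decoy)
  axes <- lapply(hel, helix_axis)
  u1 <- axes[[1L]]$direction
  dirs <- t(vapply(axes, function(a) {
    if (sum(a$direction * u1) < 0) -a$direction else a$direction
  }, numeric(3)))
  v <- vunit(colMeans(dirs))
  smoothed <- lapply(hel, smooth_minor_helix)
  pts <- do.call(rbind, smoothed)
  ctr <- colMeans(pts)
  rel <- sweep(pts, 2, ctr)
  perp <- rel - outer(as.vector(rel %*% v), v)
  mean(sqrt(rowSums(perp^2)))
}

#' Measure the superhelical pitch from a long single-chain generation
#'
#' Averages out the minor helix, fits the superhelical axis direction by
#' principal components, unwraps the azimuthal phase of the axis curve
#' about that direction, and reports the axial travel per 2*pi of
#' phase from a linear fit.
#'
#' @param ca m x 3 Calpha matrix of one chain (>= 150 residues so that a
#'   substantial part of a superhelical turn is spanned).
#' @return pitch in Angstroms.
#' @export
measure_pitch <- function(ca) {
  ca <- as.matrix(ca)
  if (nrow(ca) < 150L) {
    stop("trace too short to fit a pitch; generate >= 150 residues")
  }
  ax <- smooth_minor_helix(ca)
  rel <- sweep(ax, 2, colMeans(ax))
  v0 <- svd(rel)$v[, 1L]
  if (sum((ax[nrow(ax), ] - ax[1L, ]) * v0) < 0) v0 <- -v0
  # refine the axis by a cylinder fit: the true superhelical axis makes
  # the radial distance of the axis curve constant
  objective <- function(par) {
    v <- c(sin(par[1L]) * cos(par[2L]), sin(par[1L]) * sin(par[2L]), cos(par[1L]))
    rr <- sweep(rel, 2, c(par[3L], par[4L], 0))
    perp <- rr - outer(as.vector(rr %*% v), v)
    stats::var(sqrt(rowSums(perp^2)))
  }
  p0 <- c(acos(max(-1, min(1, v0[3L]))), atan2(v0[2L], v0[1L]), 0, 0)
  fit <- stats::optim(p0, objective,
                      control = list(maxit = 2000, reltol = 1e-12))
  par <- fit$par
  v <- c(sin(par[1L]) * cos(par[2L]), sin(par[1L]) * sin(par[2L]), cos(par[1L]))
  rr <- sweep(rel, 2, c(par[3L], par[4L], 0))
  ref <- if (abs(v[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- vunit(vcross(v, ref))
  e2 <- vcross(v, e1)
  th <- atan2(as.vector(rr %*% e2), as.vector(rr %*% e1))
  dth <- diff(th)
  dth <- (dth + pi) %% (2 * pi) - pi
  phase <- cumsum(c(th[1L], dth))
  z <- as.vector(rr %*% v)
  cf <- stats::lm.fit(cbind(1, phase), z)
  unname(abs(cf$coefficients[2L])) * 2 * pi
}
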