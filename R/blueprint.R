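# Blueprint-driven sequence-independent backbone building.
#
# A blueprint is a per-residue table of secondary structure (H/L) and
# ABEGO letter. Backbones are assembled by giving helix positions the
# ideal helix dihedrals and loop positions torsions drawn from the
# shipped loop tables (exact in representative mode, noisy with
# in-bin rejection in sampled mode), then building Cartesian
# coordinates from internal coordinates. A Calpha clash filter stands
# in for a steric score.

#' Construct a three-helix blueprint
#'
#' @param l1,h,l3 helix lengths in residues (>= 5).
#' @param loop1,loop2 loop ABEGO strings (non-empty, letters A/B/E/G).
#' @return data.frame of class `blueprint` with columns `pos`, `aa`
#'   (always "V"), `ss` ("H"/"L"), `abego`.
#' @export
make_blueprint <- function(l1, h, l3, loop1, loop2) {
  if (min(l1, h, l3) < 5L) stop("helix lengths must be >= 5 residues")
  if (nchar(loop1) < 1L || nchar(loop2) < 1L) stop("loop strings must be non-empty")
  ss <- c(rep("H", l1), rep("L", nchar(loop1)), rep("H", h),
          rep("L", nchar(loop2)), rep("H", l3))
  abego <- c(rep("A", l1), strsplit(loop1, "")[[1L]], rep("A", h),
             strsplit(loop2, "")[[1L]], rep("A", l3))
  if (!all(abego %in% c("A", "B", "E", "G"))) {
    stop("loop ABEGO letters must be in {A, B, E, G}")
  }
  structure(data.frame(pos = seq_along(ss), aa = "V", ss = ss, abego = abego,
                       stringsAsFactors = FALSE),
            class = c("blueprint", "data.frame"))
}

#' Parse a blueprint file
#'
#' Accepts whitespace-separated lines `index residue SSABEGO [flag]`
#' (e.g. "1 V HA"); the optional trailing remodel flag is ignored.
#'
#' @param path file path.
#' @return a `blueprint` data.frame.
#' @export
parse_blueprint <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\\s+")[[1L]]
    if (length(f) < 3L) stop("malformed blueprint line ", i, ": '", lines[i], "'")
    ss <- substr(f[3L], 1L, 1L)
    if (!ss %in% c("H", "L")) {
      stop("unsupported secondary-structure letter '", ss, "' on line ", i)
    }
    abego <- if (nchar(f[3L]) >= 2L) substr(f[3L], 2L, 2L) else
      if (ss == "H") "A" else stop("loop line ", i, " lacks an ABEGO letter")
    data.frame(pos = as.integer(f[1L]), aa = f[2L], ss = ss, abego = abego,
               stringsAsFactors = FALSE)
  })
  bp <- do.call(rbind, rows)
  if (any(diff(bp$pos) != 1L)) stop("blueprint positions must increase by 1")
  structure(bp, class = c("blueprint", "data.frame"))
}

#' Write a blueprint file
#' @param bp a `blueprint`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_blueprint <- function(bp, path) {
  writeLines(sprintf("%d V %s%s", bp$pos, bp$ss, bp$abego), path)
  invisible(path)
}

#' Segment decomposition of a blueprint
#' @param bp a `blueprint`.
#' @return data.frame with one row per segment: `type` (H/L), `start`,
#'   `end`, `length`, `abego` (string for loops, "A..." for helices).
#' @export
blueprint_segments <- function(bp) {
  r <- rle(bp$ss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(type = r$values, start = starts, end = ends, length = r$lengths,
             abego = vapply(seq_along(starts), function(k) {
               paste(bp$abego[starts[k]:ends[k]], collapse = "")
             }, ""), stringsAsFactors = FALSE)
}

#' Assemble a backbone from a blueprint
#'
#' Helix positions receive the ideal helix dihedrals (plus optional
#' Gaussian noise); loop segments receive torsions from
#' [loop_torsions()]. Representative mode is fully deterministic.
#'
#' @param bp a `blueprint`.
#' @param mode "representative" (shipped table values) or "sampled"
#'   (in-bin Gaussian noise, uses the session RNG).
#' @param loop_sigma loop torsion noise sd in degrees (sampled mode).
#' @param helix_sigma helix torsion noise sd in degrees (sampled mode;
#'   0 keeps helices ideal).
#' @param mirrored if TRUE, negate every phi and psi before building,
#'   producing the exact mirror-image backbone.
#' @return a `backbone_chain` with attribute `segments` (the blueprint
#'   decomposition).
#' @export
assemble_backbone <- function(bp, mode = c("representative", "sampled"),
                              loop_sigma = 10, helix_sigma = 0,
                              mirrored = FALSE) {
  mode <- match.arg(mode)
  seg <- blueprint_segments(bp)
  n <- nrow(bp)
  ideal <- ideal_helix_dihedrals()
  d <- data.frame(phi = rep(ideal[["phi"]], n), psi = rep(ideal[["psi"]], n),
                  omega = 180)
  if (mode == "sampled" && helix_sigma > 0) {
    hsel <- bp$ss == "H"
    d$phi[hsel] <- d$phi[hsel] + stats::rnorm(sum(hsel), 0, helix_sigma)
    d$psi[hsel] <- d$psi[hsel] + stats::rnorm(sum(hsel), 0, helix_sigma)
  }
  for (k in which(seg$type == "L")) {
    lt <- loop_torsions(seg$abego[k], mode = mode, sigma = loop_sigma)
    idx <- seg$start[k]:seg$end[k]
    d$phi[idx] <- lt$phi
    d$psi[idx] <- lt$psi
  }
  if (mirrored) {
    d$phi <- -d$phi
    d$psi <- -d$psi
  }
  chain <- build_backbone(d, id = "assembled")
  attr(chain, "segments") <- seg
  chain
}

#' Calpha steric check
#'
#' @param chain a `backbone_chain` or Calpha matrix.
#' @param threshold clash distance in Angstroms (default 3.5).
#' @return TRUE when no Calpha pair separated by >= 3 residues lies
#'   closer than the threshold (i.e. the chain is clash-free).
#' @export
clash_check <- function(chain, threshold = 3.5) {
  ca <- if (inherits(chain, "backbone_chain")) chain$CA else as.matrix(chain)
  n <- nrow(ca)
  if (n < 4L || threshold <= 0) return(TRUE)
  for (i in 1:(n - 3L)) {
    rest <- ca[(i + 3L):n, , drop = FALSE]
    d2 <- rowSums(sweep(rest, 2, ca[i, ])^2)
    if (any(d2 < threshold^2)) return(FALSE)
  }
  TRUE
}

# Row indices of a chain's helix residues, from its blueprint segments.
helix_indices <- function(seg) {
  unlist(lapply(which(seg$type == "H"), function(k) seg$start[k]:seg$end[k]))
}

#' Scan the second-helix length of a three-helix blueprint
#'
#' For each H in the range, a blueprint helix(l1)-loop1-helix(H)-loop2-
#' helix(l3) is built `n_trajectories` times; clash-free conformations
#' are TM-scored against ideal CW and CCW three-helix reference decoys
#' with matching helix lengths (loop residues are excluded from the
#' correspondence: the references have none). Fractions use the strict
#' TM > threshold rule with all attempted trajectories in the
#' denominator.
#'
#' @param l1,l3 first/third helix lengths (default 14).
#' @param loop1,loop2 loop ABEGO strings (default "GB").
#' @param h_range integer vector of second-helix lengths (default 5:20).
#' @param n_trajectories builds per H (default 1; representative mode
#'   is deterministic, so more only matters in sampled mode).
#' @param mode,loop_sigma,helix_sigma passed to [assemble_backbone()].
#' @param threshold folded TM cut-off (default 0.55).
#' @param variant reference radius variant (default 0.75: of the
#'   standard radius-variant series, the reference scale closest to the
#'   inter-helix packing distances the torsion-space builder actually
#'   produces; 1.00 is the base scale).
#' @param clash_threshold Calpha clash distance (default 3.5 A).
#' @param mirrored build mirror-image conformations (see
#'   [assemble_backbone()]).
#' @return data.frame of class `foldability_result`: H, frac_CW,
#'   frac_CCW, best_TM_CW, best_TM_CCW, n_attempted, n_clash.
#' @export
scan_second_helix <- function(l1 = 14, loop1 = "GB", l3 = 14, loop2 = "GB",
                              h_range = 5:20, n_trajectories = 1,
                              mode = "representative", loop_sigma = 10,
                              helix_sigma = 0, threshold = 0.55,
                              variant = 0.75, clash_threshold = 3.5,
                              mirrored = FALSE) {
  rows <- lapply(h_range, function(h) {
    bp <- make_blueprint(l1, h, l3, loop1, loop2)
    seg <- blueprint_segments(bp)
    hseg <- which(seg$type == "H")
    model_hel <- lapply(hseg, function(k) seg$start[k]:seg$end[k])
    lens <- c(l1, h, l3)
    ref_ends <- cumsum(lens)
    ref_starts <- c(1L, utils::head(ref_ends, -1L) + 1L)
    ref_hel <- lapply(1:3, function(k) ref_starts[k]:ref_ends[k])
    ref_cw <- make_reference_bundle(lens, "CW", variant)
    ref_ccw <- mirror_bundle(ref_cw)
    sc_cw <- sc_ccw <- numeric(0)
    n_clash <- 0L
    for (k in seq_len(n_trajectories)) {
      chain <- assemble_backbone(bp, mode = mode, loop_sigma = loop_sigma,
                                 helix_sigma = helix_sigma, mirrored = mirrored)
      if (!clash_check(chain, clash_threshold)) {
        n_clash <- n_clash + 1L
        next
      }
      sc_cw <- c(sc_cw, tm_score_registered(chain$CA, ref_cw$ca,
                                            model_hel, ref_hel)$score)
      sc_ccw <- c(sc_ccw, tm_score_registered(chain$CA, ref_ccw$ca,
                                              model_hel, ref_hel)$score)
    }
    if (length(sc_cw) == 0L) {
      warning("all trajectories clashed for H = ", h)
    }
    data.frame(H = h,
               frac_CW = sum(sc_cw > threshold) / n_trajectories,
               frac_CCW = sum(sc_ccw > threshold) / n_trajectories,
               best_TM_CW = if (length(sc_cw)) max(sc_cw) else NA_real_,
               best_TM_CCW = if (length(sc_ccw)) max(sc_ccw) else NA_real_,
               n_attempted = n_trajectories, n_clash = n_clash)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("foldability_result", "data.frame")
  out
}
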