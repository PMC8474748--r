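# Shipped loop torsion tables.
#
# Representative-mode backbone building needs concrete (phi, psi)
# values for loop residues. Two levels are shipped:
#
#  * a per-motif table for the recurrent hairpin loops (GB, GBB, BAAB,
#    BAB), with one variant per packing handedness. Each variant was
#    fixed once by sampling torsions inside the motif's ABEGO bins and
#    keeping a combination that closes a tight hairpin (theta_HH well
#    below the 60 degree cut) with an unambiguous phi_HH sign and no
#    backbone clash; the majority variant of each motif reproduces the
#    handedness the motif shows in natural structures (GB and BAAB
#    left-handed, GBB right-handed; BAB supports both, which is what
#    makes its handedness ambiguous).
#  * a per-letter fallback at the bin centres, used for loop strings
#    with no motif entry.
#
# Every stored value classifies back to its own ABEGO letter (enforced
# by a test), so representative-mode builds always honour the
# blueprint.

.loop_letter_table <- list(
  A = c(phi = -63.0, psi = -41.0),
  B = c(phi = -135.0, psi = 135.0),
  G = c(phi = 64.0, psi = 35.0),
  E = c(phi = 64.0, psi = 155.0)
)

.loop_motif_table <- list(
  GB = list(
    L = data.frame(phi = c(96.6, -171.6), psi = c(99.0, 112.8)),
    R = data.frame(phi = c(109.8, -167.7), psi = c(55.0, 71.1))
  ),
  GBB = list(
    L = data.frame(phi = c(89.6, -170.6, -174.9), psi = c(30.9, 89.4, 68.8)),
    R = data.frame(phi = c(27.4, -47.1, -74.8), psi = c(-16.1, -163.2, 174.1))
  ),
  BAAB = list(
    L = data.frame(phi = c(-98.6, -102.9, -56.4, -169.3),
                   psi = c(68.4, 10.2, 43.6, 141.0)),
    R = data.frame(phi = c(-75.3, -137.3, -134.7, -85.4),
                   psi = c(107.7, -50.8, -63.4, 122.8))
  ),
  BAB = list(
    L = data.frame(phi = c(-151.0, -83.0, -58.0), psi = c(146.0, 47.7, 136.6)),
    R = data.frame(phi = c(-81.7, -95.2, -81.4), psi = c(121.6, -56.4, 169.3))
  )
)

# majority packing handedness of each shipped motif
.motif_majority <- c(GB = "L", GBB = "R", BAAB = "L", BAB = "L")

#' Shipped loop torsion tables
#'
#' @return list with `motifs` (per-motif, per-handedness data.frames of
#'   loop phi/psi in degrees), `majority` (the natural majority
#'   handedness per motif) and `letters` (per-letter fallback values).
#' @export
loop_torsion_table <- function() {
  list(motifs = .loop_motif_table, majority = .motif_majority,
       letters = .loop_letter_table)
}

#' Sample (or look up) loop dihedrals for one ABEGO letter
#'
#' Representative mode returns the shipped per-letter value;
#' sampled mode adds Gaussian noise and redraws until the perturbed
#' torsion still classifies as the requested letter, so the blueprint
#' letter is honoured by construction.
#'
#' @param letter one of "A", "B", "E", "G" ("O" is unsupported).
#' @param mode "representative" or "sampled".
#' @param sigma noise standard deviation in degrees (sampled mode).
#' @return named numeric c(phi, psi, omega).
#' @export
sample_loop_dihedrals <- function(letter, mode = c("representative", "sampled"),
                                  sigma = 10) {
  mode <- match.arg(mode)
  if (!letter %in% names(.loop_letter_table)) {
    stop("unsupported ABEGO letter '", letter, "' for loop sampling")
  }
  base <- .loop_letter_table[[letter]]
  if (mode == "representative") {
    return(c(base, omega = 180))
  }
  for (k in 1:2000) {
    cand <- base + stats::rnorm(2, 0, sigma)
    if (identical(assign_abego(cand[1L], cand[2L]), letter)) {
      return(c(phi = unname(cand[1L]), psi = unname(cand[2L]), omega = 180))
    }
  }
  stop("could not sample a torsion inside the '", letter, "' bin")
}

#' Loop torsions for a whole ABEGO string
#'
#' Looks the string up in the shipped motif table (using the requested
#' or the motif's natural majority handedness); strings without a motif
#' entry fall back to per-letter values. In sampled mode Gaussian noise
#' is added per torsion and the draw is rejected until every residue
#' still classifies to its blueprint letter.
#'
#' @param abego loop ABEGO string (letters in A/B/E/G).
#' @param mode "representative" or "sampled".
#' @param sigma noise sd in degrees (sampled mode).
#' @param handedness "L", "R", or NULL for the motif's majority
#'   (ignored for strings without a motif entry).
#' @return data.frame with columns phi, psi, omega (one row per loop
#'   residue).
#' @export
loop_torsions <- function(abego, mode = c("representative", "sampled"),
                          sigma = 10, handedness = NULL) {
  mode <- match.arg(mode)
  letters_vec <- strsplit(abego, "")[[1L]]
  if (!all(letters_vec %in% names(.loop_letter_table))) {
    stop("loop ABEGO string '", abego, "' contains unsupported letters")
  }
  if (abego %in% names(.loop_motif_table)) {
    hand <- if (is.null(handedness)) .motif_majority[[abego]] else handedness
    base <- .loop_motif_table[[abego]][[hand]]
  } else {
    base <- do.call(rbind, lapply(letters_vec, function(L) {
      as.data.frame(as.list(.loop_letter_table[[L]]))
    }))
  }
  if (mode == "representative") {
    return(data.frame(phi = base$phi, psi = base$psi, omega = 180))
  }
  n <- nrow(base)
  for (k in 1:2000) {
    phi <- base$phi + stats::rnorm(n, 0, sigma)
    psi <- base$psi + stats::rnorm(n, 0, sigma)
    if (identical(assign_abego(phi, psi), letters_vec)) {
      return(data.frame(phi = phi, psi = psi, omega = 180))
    }
  }
  stop("could not sample loop torsions for '", abego, "' within its bins")
}
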