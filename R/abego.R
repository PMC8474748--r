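#' ABEGO classification of backbone torsions
#'
#' Five-state coarse-graining of the Ramachandran plane plus the cis
#' peptide bond: A (alpha-helical region), B (beta/extended), G
#' (left-handed helical), E (remaining positive-phi region), O (cis
#' omega). The boundaries follow the Rosetta convention:
#' O if |omega| < 90; otherwise for phi < 0, A if -75 <= psi < 50 and B
#' elsewhere; for phi >= 0, G if -100 < psi <= 100 and E elsewhere.
#' The four trans-omega regions tile the whole (phi, psi) plane.
#'
#' @param phi,psi,omega numeric vectors of torsions in degrees (recycled
#'   to a common length). `omega` defaults to trans (180).
#' @return character vector of single letters in {A, B, E, G, O}; NA in
#'   any torsion yields NA (terminal residues carry no letter).
#' @export
assign_abego <- function(phi, psi, omega = 180) {
  k <- max(length(phi), length(psi), length(omega))
  phi <- rep_len(wrap_angle(phi), k)
  psi <- rep_len(wrap_angle(psi), k)
  omega <- rep_len(wrap_angle(omega), k)
  out <- rep(NA_character_, k)
  def <- !is.na(phi) & !is.na(psi) & !is.na(omega)
  cis <- def & abs(omega) < 90
  out[cis] <- "O"
  tr <- def & !cis
  neg <- tr & phi < 0
  out[neg & psi >= -75 & psi < 50] <- "A"
  out[neg & !(psi >= -75 & psi < 50)] <- "B"
  pos <- tr & phi >= 0
  out[pos & psi > -100 & psi <= 100] <- "G"
  out[pos & !(psi > -100 & psi <= 100)] <- "E"
  out
}

#' ABEGO string of a backbone chain
#'
#' @param chain a `backbone_chain`.
#' @param idx optional residue indices to report (default: all).
#' @return character vector of per-residue letters (NA where a torsion
#'   is undefined, i.e. at chain termini).
#' @export
abego_letters <- function(chain, idx = NULL) {
  d <- measure_dihedrals(chain)
  letters <- assign_abego(d$phi, d$psi, d$omega)
  if (!is.null(idx)) letters[idx] else letters
}
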