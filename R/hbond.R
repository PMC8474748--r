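# Backbone hydrogen bonds by the DSSP (Kabsch-Sander) electrostatic
# model. Amide hydrogens are reconstructed geometrically: H sits 1 A
# from N along the direction of the preceding residue's C=O bond
# (O -> C), the standard DSSP placement. The bond energy between donor
# N-H (residue i) and acceptor C=O (residue j) is
#   E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)  kcal/mol,
# and pairs with E < -0.5 kcal/mol are reported.

ks_hbond_energy <- function(N, H, C, O) {
  rON <- vnorm(O - N); rCH <- vnorm(C - H)
  rOH <- vnorm(O - H); rCN <- vnorm(C - N)
  if (min(rON, rCH, rOH, rCN) < 0.5) return(-9.9)  # clamped, as in DSSP
  max(-9.9, 0.084 * 332 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN))
}

#' Backbone hydrogen bonds of a chain (Kabsch-Sander energy)
#'
#' @param chain a `backbone_chain` with O atoms.
#' @param subset optional integer residue range; only bonds with donor
#'   or acceptor inside `subset` (extended by `flank`) are reported.
#' @param flank residues added on each side of `subset` (default 2).
#' @param cutoff report bonds with energy strictly below this value
#'   (default -0.5 kcal/mol).
#' @return data.frame with columns `donor`, `acceptor`, `energy`
#'   (kcal/mol), sorted by energy.
#' @export
kabsch_sander_hbonds <- function(chain, subset = NULL, flank = 2,
                                 cutoff = -0.5) {
  if (!inherits(chain, "backbone_chain")) stop("expected a backbone_chain")
  if (is.null(chain$O) || anyNA(chain$O)) {
    stop("hydrogen-bond analysis requires carbonyl O atoms for every residue")
  }
  n <- chain$n
  keep <- if (is.null(subset)) seq_len(n) else {
    intersect(seq_len(n), (min(subset) - flank):(max(subset) + flank))
  }
  H <- matrix(NA_real_, n, 3)
  for (i in 2:n) {
    co <- chain$C[i - 1L, ] - chain$O[i - 1L, ]
    H[i, ] <- chain$N[i, ] + co / vnorm(co)
  }
  rows <- list()
  for (i in 2:n) {          # donor N-H of residue i
    for (j in seq_len(n)) { # acceptor C=O of residue j
      if (abs(i - j) < 2L) next
      if (!(i %in% keep) && !(j %in% keep)) next
      if (vnorm(chain$CA[i, ] - chain$CA[j, ]) > 9) next
      e <- ks_hbond_energy(chain$N[i, ], H[i, ], chain$C[j, ], chain$O[j, ])
      if (e < cutoff) {
        rows[[length(rows) + 1L]] <- data.frame(donor = i, acceptor = j,
                                                energy = e)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(donor = integer(), acceptor = integer(),
                      energy = numeric()))
  }
  out <- do.call(rbind, rows)
  out[order(out$energy), , drop = FALSE]
}

#' Hydrogen bonds stabilizing a hairpin loop
#'
#' Reports backbone hydrogen bonds with at least one partner in the
#' fragment's loop (plus two flanking residues on each side) -- the
#' network that makes recurrent loop conformations rigid.
#'
#' @param frag an `hlh_fragment` whose chain carries O atoms.
#' @param cutoff energy cut-off in kcal/mol (default -0.5, strict).
#' @return data.frame as in [kabsch_sander_hbonds()].
#' @export
loop_hbond_network <- function(frag, cutoff = -0.5) {
  kabsch_sander_hbonds(frag$chain, subset = frag$loop_range, flank = 2,
                       cutoff = cutoff)
}
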