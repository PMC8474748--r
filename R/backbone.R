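#' Ideal backbone covalent geometry
#'
#' Bond lengths (Angstroms) and bond angles (degrees) used when building
#' chains from internal coordinates. The values are the canonical
#' Engh-Huber-style means for protein backbones; with the ideal helix
#' dihedrals they yield an alpha-helix with ~1.5 A rise and ~3.6
#' residues per turn.
#'
#' @return named list of bond lengths and angles.
#' @export
ideal_backbone_geometry <- function() {
  list(
    b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
    a_n_ca_c = 111.2, a_ca_c_n = 117.2, a_c_n_ca = 121.7, a_ca_c_o = 120.1
  )
}

#' Ideal alpha-helix dihedrals
#' @return named numeric c(phi, psi, omega) in degrees.
#' @export
ideal_helix_dihedrals <- function() c(phi = -57, psi = -47, omega = 180)

#' Construct a backbone chain object
#'
#' @param N,CA,C n x 3 coordinate matrices (Angstroms).
#' @param O optional n x 3 matrix of carbonyl oxygens.
#' @param id chain label.
#' @return an object of class `backbone_chain` with elements `id`, `n`,
#'   and the coordinate matrices.
#' @export
backbone_chain <- function(N, CA, C, O = NULL, id = "chain") {
  N <- as.matrix(N); CA <- as.matrix(CA); C <- as.matrix(C)
  n <- nrow(CA)
  if (nrow(N) != n || nrow(C) != n || ncol(N) != 3 || ncol(CA) != 3 || ncol(C) != 3) {
    stop("N, CA, C must be n x 3 matrices of equal row count")
  }
  if (!all(is.finite(N)) || !all(is.finite(CA)) || !all(is.finite(C))) {
    stop("backbone coordinates must be finite")
  }
  if (!is.null(O)) {
    O <- as.matrix(O)
    if (nrow(O) != n) stop("O must match the number of residues")
  }
  structure(list(id = id, n = n, N = N, CA = CA, C = C, O = O),
            class = "backbone_chain")
}

#' @export
print.backbone_chain <- function(x, ...) {
  cat(sprintf("<backbone_chain '%s': %d residues%s>\n", x$id, x$n,
              if (is.null(x$O)) ", no O atoms" else ""))
  invisible(x)
}

#' @export
length.backbone_chain <- function(x) x$n

#' Extract a contiguous residue range as a new chain
#' @param chain a `backbone_chain`.
#' @param idx integer residue indices (must be contiguous ascending).
#' @return a `backbone_chain` over the sub-range (re-indexed from 1).
#' @export
subchain <- function(chain, idx) {
  idx <- as.integer(idx)
  if (any(diff(idx) != 1L)) stop("subchain indices must be contiguous ascending")
  backbone_chain(chain$N[idx, , drop = FALSE], chain$CA[idx, , drop = FALSE],
                 chain$C[idx, , drop = FALSE],
                 if (!is.null(chain$O)) chain$O[idx, , drop = FALSE],
                 id = chain$id)
}

normalize_dihedral_input <- function(dihedrals) {
  if (is.matrix(dihedrals)) dihedrals <- as.data.frame(dihedrals)
  if (!is.data.frame(dihedrals) || !all(c("phi", "psi") %in% names(dihedrals))) {
    stop("dihedrals must be a data.frame with columns phi, psi (and optionally omega)")
  }
  if (nrow(dihedrals) == 0L) stop("need at least 2 residues to build a chain")
  if (is.null(dihedrals$omega)) dihedrals$omega <- 180
  dihedrals[, c("phi", "psi", "omega")]
}

#' Build a backbone chain from internal coordinates
#'
#' Sequential NeRF-style placement: atoms are appended one by one in a
#' canonical frame (N1 at the origin, CA1 on +x, C1 in the xy plane), so
#' the construction is deterministic. Residue i consumes phi(i), psi(i)
#' and omega(i), where omega(i) is the CA(i-1)-C(i-1)-N(i)-CA(i) torsion
#' of the peptide bond preceding residue i; phi(1), psi(n) and omega(1)
#' are not needed and may be NA. Carbonyl oxygens are placed in the
#' peptide plane using the psi torsion (O trans to the following N), so a
#' psi value is still consumed for the last residue.
#'
#' @param dihedrals data.frame with columns `phi`, `psi`, `omega`
#'   (degrees); one row per residue, >= 2 rows.
#' @param geometry bond-length/angle set, see [ideal_backbone_geometry()].
#' @param id chain label.
#' @return a `backbone_chain` with N, CA, C and O coordinates.
#' @examples
#' h <- as.data.frame(as.list(ideal_helix_dihedrals()))
#' chain <- build_backbone(h[rep(1, 12), ])
#' @export
build_backbone <- function(dihedrals, geometry = ideal_backbone_geometry(),
                           id = "built") {
  d <- normalize_dihedral_input(dihedrals)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 residues to build a chain")
  used <- c(d$phi[-1L], d$psi, d$omega[-1L])
  if (any(!is.finite(used))) stop("non-finite dihedral angle in input")
  g <- geometry
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(g$b_n_ca, 0, 0)
  # C1 in the xy plane, making the ideal N-CA-C angle with the CA->N bond
  ang <- deg2rad(180 - g$a_n_ca_c)
  C[1L, ] <- CA[1L, ] + g$b_ca_c * c(cos(ang), sin(ang), 0)
  for (i in seq_len(n)[-1L]) {
    N[i, ] <- place_atom(N[i - 1L, ], CA[i - 1L, ], C[i - 1L, ],
                         g$b_c_n, g$a_ca_c_n, d$psi[i - 1L])
    CA[i, ] <- place_atom(CA[i - 1L, ], C[i - 1L, ], N[i, ],
                          g$b_n_ca, g$a_c_n_ca, d$omega[i])
    C[i, ] <- place_atom(C[i - 1L, ], N[i, ], CA[i, ],
                         g$b_ca_c, g$a_n_ca_c, d$phi[i])
  }
  for (i in seq_len(n)) {
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         g$b_c_o, g$a_ca_c_o, d$psi[i] + 180)
  }
  backbone_chain(N, CA, C, O, id = id)
}

#' Measure backbone dihedral angles
#'
#' phi(i) = C(i-1)-N(i)-CA(i)-C(i); psi(i) = N(i)-CA(i)-C(i)-N(i+1);
#' omega(i) = CA(i-1)-C(i-1)-N(i)-CA(i). Angles undefined at the termini
#' (phi/omega of residue 1, psi of residue n) are reported as NA.
#'
#' @param chain a `backbone_chain` with complete N, CA, C.
#' @return data.frame with columns `phi`, `psi`, `omega` in degrees in
#'   (-180, 180], one row per residue.
#' @export
measure_dihedrals <- function(chain) {
  if (!inherits(chain, "backbone_chain")) stop("expected a backbone_chain")
  n <- chain$n
  if (n < 2L) stop("need at least 2 residues")
  if (anyNA(chain$N) || anyNA(chain$CA) || anyNA(chain$C)) {
    stop("missing backbone atom coordinates; fragment rejected")
  }
  phi <- psi <- omega <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1L) {
      phi[i] <- dihedral_angle(chain$C[i - 1L, ], chain$N[i, ],
                               chain$CA[i, ], chain$C[i, ])
      omega[i] <- dihedral_angle(chain$CA[i - 1L, ], chain$C[i - 1L, ],
                                 chain$N[i, ], chain$CA[i, ])
    }
    if (i < n) {
      psi[i] <- dihedral_angle(chain$N[i, ], chain$CA[i, ],
                               chain$C[i, ], chain$N[i + 1L, ])
    }
  }
  data.frame(phi = phi, psi = psi, omega = omega)
}
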