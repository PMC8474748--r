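# Synthetic helix-loop-helix datasets with known ground truth.
#
# The generator emulates the statistical structure the hairpin analysis
# assumes about its natural-structure input: motif populations
# dominated by a few short recurrent loops, each with a strongly biased
# packing handedness (and one deliberately ambiguous motif). Fragments
# are built from ideal helices plus in-bin noisy loop torsions;
# minority-handedness fragments use the opposite-handedness loop
# conformer of the same ABEGO string, so every truth label is exact.

#' Specification of a synthetic fragment dataset
#'
#' @param motifs data.frame with columns `motif` (loop ABEGO string),
#'   `handedness` (majority packing handedness, "L"/"R"),
#'   `count` (fragments per motif), `ratio` (majority:minority
#'   handedness ratio; Inf for a pure motif), `sigma` (loop torsion
#'   noise sd, degrees).
#' @param helix_length flanking helix length in residues.
#' @param seed RNG seed used by [generate_fragment_dataset()].
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(motifs, helix_length = 14, seed = 1) {
  stopifnot(is.data.frame(motifs),
            all(c("motif", "handedness", "count", "ratio", "sigma") %in%
                  names(motifs)))
  if (any(motifs$count < 0) || any(motifs$sigma < 0)) {
    stop("counts and noise levels must be non-negative")
  }
  if (any(motifs$ratio < 1)) stop("ratio is majority:minority, >= 1")
  structure(list(motifs = motifs, helix_length = helix_length, seed = seed),
            class = "synthetic_spec")
}

#' Default engineered dataset specification
#'
#' Four motifs at 100 fragments each with 5 degree loop noise: GB
#' (10:1 left-handed), BAB (1.2:1, deliberately ambiguous), GBB (8:1
#' right-handed) and BAAB (7:1 left-handed). Under the ratio-5 selection
#' rule this yields exactly {GB, GBB, BAAB} with BAB rejected.
#'
#' @param count fragments per motif (default 100).
#' @param sigma loop torsion noise sd in degrees (default 5).
#' @param seed RNG seed.
#' @return a `synthetic_spec`.
#' @export
default_synthetic_spec <- function(count = 100, sigma = 5, seed = 1) {
  synthetic_spec(data.frame(
    motif = c("GB", "BAB", "GBB", "BAAB"),
    handedness = c("L", "L", "R", "L"),
    count = count,
    ratio = c(10, 1.2, 8, 7),
    sigma = sigma,
    stringsAsFactors = FALSE
  ), seed = seed)
}

# Build one fragment with the requested loop string and handedness;
# torsions are rejection-sampled until the ABEGO letters and the
# phi_HH sign both match (exact truth labels by construction).
build_labelled_fragment <- function(motif, handedness, sigma, helix_length,
                                    id) {
  lets <- strsplit(motif, "")[[1L]]
  want_sign <- if (handedness == "L") -1 else 1
  base <- loop_torsions(motif, mode = "representative",
                        handedness = handedness)
  l1 <- helix_length
  nl <- length(lets)
  n <- 2L * l1 + nl
  loop_idx <- (l1 + 1L):(l1 + nl)
  ideal <- ideal_helix_dihedrals()
  for (try in 1:500) {
    phi <- base$phi + stats::rnorm(nl, 0, sigma)
    psi <- base$psi + stats::rnorm(nl, 0, sigma)
    if (!identical(assign_abego(phi, psi), lets)) next
    d <- data.frame(phi = rep(ideal[["phi"]], n), psi = rep(ideal[["psi"]], n),
                    omega = 180)
    d$phi[loop_idx] <- phi
    d$psi[loop_idx] <- psi
    chain <- build_backbone(d, id = id)
    frag <- hlh_fragment(chain, 1:l1, loop_idx, (l1 + nl + 1L):n,
                         id = id, source = "synthetic")
    if (frag$loop_abego != motif) next
    g <- compute_geometry(frag)
    if (sign(g$phi_HH) != want_sign) next
    return(frag)
  }
  stop("could not generate a ", handedness, "-handed '", motif,
       "' fragment: the motif table is inconsistent with its own labels")
}

#' Generate a synthetic fragment dataset with truth labels
#'
#' @param spec a `synthetic_spec`.
#' @return list with `fragments` (list of `hlh_fragment`) and `truth`
#'   (data.frame: id, motif, handedness, sigma). Deterministic for a
#'   fixed spec (the spec carries the seed).
#' @export
generate_fragment_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  fragments <- list()
  truth <- list()
  for (r in seq_len(nrow(spec$motifs))) {
    row <- spec$motifs[r, ]
    n_minor <- if (is.infinite(row$ratio)) 0L else
      as.integer(round(row$count / (row$ratio + 1)))
    n_major <- row$count - n_minor
    hands <- c(rep(row$handedness, n_major),
               rep(setdiff(c("L", "R"), row$handedness), n_minor))
    for (k in seq_along(hands)) {
      id <- sprintf("%s_%03d", row$motif, k)
      frag <- build_labelled_fragment(row$motif, hands[k], row$sigma,
                                      spec$helix_length, id)
      fragments[[length(fragments) + 1L]] <- frag
      truth[[length(truth) + 1L]] <- data.frame(
        id = id, motif = row$motif, handedness = hands[k],
        sigma = row$sigma, stringsAsFactors = FALSE)
    }
  }
  list(fragments = fragments, truth = do.call(rbind, truth))
}

#' Build a toy multi-segment chain with a known secondary structure
#'
#' @param plan data.frame with columns `type` ("H"/"L") and `length`;
#'   loops may carry an `abego` string column (default: "B" repeated).
#'   Shorthand: a character plan like "H12-L2-H12" is also accepted.
#' @return list with `chain` (a `backbone_chain`) and `ss` (character
#'   track matching the plan exactly).
#' @export
generate_toy_chain <- function(plan) {
  if (is.character(plan)) {
    parts <- strsplit(plan, "-")[[1L]]
    plan <- data.frame(type = substr(parts, 1L, 1L),
                       length = as.integer(substring(parts, 2L)),
                       stringsAsFactors = FALSE)
  }
  if (!all(plan$type %in% c("H", "L"))) stop("plan segments must be H or L")
  if (is.null(plan$abego)) plan$abego <- NA_character_
  ideal <- ideal_helix_dihedrals()
  phi <- psi <- numeric(0)
  ss <- character(0)
  for (k in seq_len(nrow(plan))) {
    len <- plan$length[k]
    if (plan$type[k] == "H") {
      phi <- c(phi, rep(ideal[["phi"]], len))
      psi <- c(psi, rep(ideal[["psi"]], len))
      ss <- c(ss, rep("H", len))
    } else {
      ab <- plan$abego[k]
      if (is.na(ab)) ab <- paste(rep("B", len), collapse = "")
      if (nchar(ab) != len) stop("loop ABEGO length mismatch in plan row ", k)
      lt <- loop_torsions(ab, mode = "representative")
      phi <- c(phi, lt$phi)
      psi <- c(psi, lt$psi)
      ss <- c(ss, rep("L", len))
    }
  }
  chain <- build_backbone(data.frame(phi = phi, psi = psi, omega = 180),
                          id = "toy")
  list(chain = chain, ss = ss)
}
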