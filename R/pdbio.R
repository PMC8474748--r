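# PDB and DSSP input/output. Reading goes through bio3d's parser;
# only backbone ATOM records (N, CA, C, O) of one chain are used.

#' Read a backbone chain from a PDB file
#'
#' Keeps N, CA, C and O ATOM records of a single chain (the first, or
#' `chain_id`), preferring altloc "A" on conflicts. Residues missing
#' any of N/CA/C are rejected.
#'
#' @param path PDB file path.
#' @param chain_id optional chain identifier.
#' @return a `backbone_chain` (O may contain NA rows if absent in the
#'   file; residues are re-indexed from 1 in file order).
#' @export
read_backbone_pdb <- function(path, chain_id = NULL) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (is.null(chain_id)) chain_id <- at$chain[1L]
  at <- at[at$chain == chain_id, , drop = FALSE]
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  at <- at[at$elety %in% c("N", "CA", "C", "O"), , drop = FALSE]
  resids <- unique(at$resno)
  n <- length(resids)
  get <- function(elety) {
    m <- matrix(NA_real_, n, 3)
    sel <- at[at$elety == elety, , drop = FALSE]
    idx <- match(sel$resno, resids)
    first <- !duplicated(idx)
    m[idx[first], ] <- as.matrix(sel[first, c("x", "y", "z")])
    m
  }
  N <- get("N"); CA <- get("CA"); C <- get("C"); O <- get("O")
  if (anyNA(N) || anyNA(CA) || anyNA(C)) {
    stop("missing backbone atom (N/CA/C) in ", basename(path),
         ": fragment rejected")
  }
  backbone_chain(N, CA, C, if (anyNA(O)) NULL else O,
                 id = sub("\\.pdb$", "", basename(path)))
}

fmt_atom <- function(serial, name, resno, x, chain = "A", resid = "VAL") {
  sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
          resid, chain, resno, x[1L], x[2L], x[3L])
}

#' Write a backbone chain as a PDB file
#'
#' Emits ATOM records for N, CA, C (and O when present) with residue
#' type VAL, chain A, sequential numbering.
#'
#' @param chain a `backbone_chain`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_backbone_pdb <- function(chain, path) {
  lines <- character(0)
  serial <- 0L
  for (i in seq_len(chain$n)) {
    for (nm in c("N", "CA", "C", "O")) {
      m <- chain[[nm]]
      if (is.null(m) || anyNA(m[i, ])) next
      serial <- serial + 1L
      lines <- c(lines, fmt_atom(serial, nm, i, m[i, ]))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a Calpha trace as a PDB file
#' @param ca m x 3 Calpha matrix or a `bundle_decoy`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ca_pdb <- function(ca, path) {
  if (inherits(ca, "bundle_decoy")) ca <- ca$ca
  ca <- as.matrix(ca)
  lines <- vapply(seq_len(nrow(ca)), function(i) {
    fmt_atom(i, "CA", i, ca[i, ])
  }, "")
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a secondary-structure track from a DSSP output file
#'
#' Parses the classic fixed-column format; DSSP classes H, G, I map to
#' H; E, B map to E; everything else to L.
#'
#' @param path DSSP file path.
#' @param chain_id optional chain identifier (column 12).
#' @return character vector of labels in {H, E, L}, one per residue.
#' @export
read_dssp <- function(path, chain_id = NULL) {
  lines <- readLines(path)
  start <- grep("^  #  RESIDUE", lines)
  if (length(start) != 1L) stop("not a recognizable DSSP file: ", path)
  body <- lines[(start + 1L):length(lines)]
  body <- body[nchar(body) >= 17]
  body <- body[substr(body, 14L, 14L) != "!"]  # chain breaks
  if (!is.null(chain_id)) body <- body[substr(body, 12L, 12L) == chain_id]
  ss <- substr(body, 17L, 17L)
  out <- rep("L", length(ss))
  out[ss %in% c("H", "G", "I")] <- "H"
  out[ss %in% c("E", "B")] <- "E"
  out
}

#' Fallback secondary-structure assignment from ABEGO letters
#'
#' Marks maximal runs of >= 5 consecutive 'A' residues as H and
#' everything else as L (no strand detection; sufficient for
#' helix-loop-helix extraction when no DSSP file is available).
#'
#' @param chain a `backbone_chain`.
#' @param min_run minimum 'A' run length labelled H (default 5).
#' @return character vector of labels in {H, L}.
#' @export
assign_ss_from_abego <- function(chain, min_run = 5) {
  letters_vec <- abego_letters(chain)
  isA <- !is.na(letters_vec) & letters_vec == "A"
  # chain termini carry no letter; extend flanking helix runs over them
  if (chain$n >= 2L) {
    if (is.na(letters_vec[1L]) && isA[2L]) isA[1L] <- TRUE
    if (is.na(letters_vec[chain$n]) && isA[chain$n - 1L]) isA[chain$n] <- TRUE
  }
  r <- rle(isA)
  out <- rep("L", chain$n)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k] && r$lengths[k] >= min_run) out[starts[k]:ends[k]] <- "H"
  }
  out
}
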