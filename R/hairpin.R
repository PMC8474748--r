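# Helix-loop-helix fragment extraction and packing-handedness geometry.
#
# A fragment is two flanking helices (>= 10 residues each after
# filtering) joined by a short loop (<= 10 residues). Its geometry is
# summarized by the orientation vectors of the final/first single turn
# of the N-/C-terminal helices (v_N, v_C), the loop displacement v_L,
# the crossing angle theta_HH and the inter-helix dihedral phi_HH whose
# sign defines the packing handedness (L/R).

#' Construct a helix-loop-helix fragment
#'
#' @param chain `backbone_chain` holding the fragment's own residues.
#' @param n_range,loop_range,c_range integer index vectors (within
#'   `chain`) of the N-helix, loop and C-helix; must be contiguous and
#'   ordered.
#' @param id fragment identifier.
#' @param source label of the originating structure.
#' @return object of class `hlh_fragment` with the loop ABEGO string in
#'   `$loop_abego`.
#' @export
hlh_fragment <- function(chain, n_range, loop_range, c_range,
                         id = "frag", source = chain$id) {
  stopifnot(inherits(chain, "backbone_chain"))
  rng <- c(n_range, loop_range, c_range)
  if (any(diff(rng) != 1L)) stop("fragment ranges must be contiguous and ordered")
  if (length(loop_range) < 1L) stop("loop must contain >= 1 residue")
  letters <- abego_letters(chain, loop_range)
  if (anyNA(letters)) stop("loop ABEGO undefined (loop touches a chain terminus)")
  structure(list(id = id, source = source, chain = chain,
                 n_range = as.integer(n_range),
                 loop_range = as.integer(loop_range),
                 c_range = as.integer(c_range),
                 loop_abego = paste(letters, collapse = "")),
            class = "hlh_fragment")
}

#' @export
print.hlh_fragment <- function(x, ...) {
  cat(sprintf("<hlh_fragment '%s': helices %d/%d, loop '%s'>\n", x$id,
              length(x$n_range), length(x$c_range), x$loop_abego))
  invisible(x)
}

#' Extract helix-loop-helix fragments from a chain
#'
#' Every pair of consecutive maximal H-runs separated by a single
#' L-run yields one fragment, kept when both helices exceed the
#' minimum helix length and the loop does not exceed the maximum loop
#' length. Consecutive fragments may share a helix.
#'
#' @param chain a `backbone_chain`.
#' @param ss character vector of per-residue labels in {H, E, L},
#'   aligned to the chain.
#' @param max_loop maximum loop length kept (default 10; longer loops
#'   are discarded).
#' @param min_helix minimum helix length kept (default 10; helices of
#'   9 or fewer residues are discarded).
#' @return list of `hlh_fragment` objects (possibly empty).
#' @export
extract_hlh_fragments <- function(chain, ss, max_loop = 10, min_helix = 10) {
  if (length(ss) != chain$n) stop("secondary-structure track must match the chain length")
  if (!all(ss %in% c("H", "E", "L"))) stop("ss labels must be in {H, E, L}")
  r <- rle(ss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  k <- 0L
  for (i in seq_along(r$values)) {
    if (i + 2L > length(r$values)) break
    if (r$values[i] != "H" || r$values[i + 1L] != "L" || r$values[i + 2L] != "H") next
    if (r$lengths[i] < min_helix || r$lengths[i + 2L] < min_helix) next
    if (r$lengths[i + 1L] > max_loop) next
    idx <- starts[i]:ends[i + 2L]
    k <- k + 1L
    frag_chain <- subchain(chain, idx)
    off <- starts[i] - 1L
    out[[k]] <- hlh_fragment(frag_chain,
                             n_range = (starts[i]:ends[i]) - off,
                             loop_range = (starts[i + 1L]:ends[i + 1L]) - off,
                             c_range = (starts[i + 2L]:ends[i + 2L]) - off,
                             id = sprintf("%s_hlh%d", chain$id, k),
                             source = chain$id)
  }
  out
}

#' Remove fragments whose loop starts or ends with ABEGO 'A'
#'
#' The A torsion bin is ambiguous between loop and helix termini, so
#' only fragments whose loop ABEGO string starts and ends with one of
#' B, E, G are retained.
#'
#' @param fragments list of `hlh_fragment`.
#' @return filtered list.
#' @export
prune_terminal_a <- function(fragments) {
  keep <- vapply(fragments, function(f) {
    s <- f$loop_abego
    first <- substr(s, 1L, 1L)
    last <- substr(s, nchar(s), nchar(s))
    first %in% c("B", "E", "G") && last %in% c("B", "E", "G")
  }, logical(1))
  fragments[keep]
}

#' Compute the packing geometry of a helix-loop-helix fragment
#'
#' v_N is the axis direction of the final single turn (last 4 Calpha)
#' of the N-terminal helix; v_C' that of the first single turn of the
#' C-terminal helix (both pointing N to C along the chain). v_L runs
#' from the last Calpha of the N-helix to the first Calpha of the
#' C-helix. theta_HH = arccos(v_N . (-v_C')), antiparallel-referenced
#' so that perfectly antiparallel packing gives 0; phi_HH is the
#' three-vector torsion about v_L between v_N and v_C', signed so that
#' left-handed packing is negative. Handedness is "L" for phi_HH < 0,
#' "R" otherwise.
#'
#' @param frag an `hlh_fragment`.
#' @return one-row data.frame: id, source, loop_abego, loop_length,
#'   theta_HH, phi_HH, handedness (plus the unit vectors as attribute
#'   `vectors`).
#' @export
compute_geometry <- function(frag) {
  ca <- frag$chain$CA
  n_turn <- utils::tail(frag$n_range, 4L)
  c_turn <- utils::head(frag$c_range, 4L)
  if (length(frag$n_range) < 4L || length(frag$c_range) < 4L) {
    stop("both helices need >= 4 residues for axis fitting")
  }
  v_n <- helix_axis(ca, n_turn)$direction
  v_cp <- helix_axis(ca, c_turn)$direction
  v_l <- ca[c_turn[1L], ] - ca[utils::tail(n_turn, 1L), ]
  theta <- vector_angle(v_n, -v_cp)
  phi <- -vector_dihedral(v_n, v_l, v_cp)
  geom <- data.frame(id = frag$id, source = frag$source,
                     loop_abego = frag$loop_abego,
                     loop_length = length(frag$loop_range),
                     theta_HH = theta, phi_HH = phi,
                     handedness = if (phi < 0) "L" else "R",
                     stringsAsFactors = FALSE)
  attr(geom, "vectors") <- list(v_N = v_n, v_C = -v_cp, v_Cprime = v_cp,
                                v_L = v_l)
  geom
}

#' Geometry table for a list of fragments
#' @param fragments list of `hlh_fragment`.
#' @return data.frame with one row per fragment (see
#'   [compute_geometry()]).
#' @export
fragment_geometry_table <- function(fragments) {
  if (length(fragments) == 0L) {
    return(data.frame(id = character(), source = character(),
                      loop_abego = character(), loop_length = integer(),
                      theta_HH = numeric(), phi_HH = numeric(),
                      handedness = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(fragments, compute_geometry))
}

#' Mirror a fragment through the yz plane
#'
#' Negates x of every backbone atom: an exact chirality flip, so
#' phi_HH is negated and the handedness label switches.
#'
#' @param frag an `hlh_fragment`.
#' @return the mirrored fragment (loop ABEGO recomputed, since torsion
#'   bins are chirality-sensitive).
#' @export
mirror_fragment <- function(frag) {
  ch <- frag$chain
  for (nm in c("N", "CA", "C", "O")) {
    if (!is.null(ch[[nm]])) ch[[nm]][, 1L] <- -ch[[nm]][, 1L]
  }
  hlh_fragment(ch, frag$n_range, frag$loop_range, frag$c_range,
               id = frag$id, source = frag$source)
}

#' Keep hairpin fragments by crossing angle
#'
#' @param fragments list of `hlh_fragment`.
#' @param theta_max threshold in degrees (default 60); fragments are
#'   kept when theta_HH is strictly less than it.
#' @param geometry optional precomputed [fragment_geometry_table()].
#' @return filtered list of fragments.
#' @export
filter_hairpins <- function(fragments, theta_max = 60, geometry = NULL) {
  if (length(fragments) == 0L) return(fragments)
  if (is.null(geometry)) geometry <- fragment_geometry_table(fragments)
  fragments[geometry$theta_HH < theta_max]
}

#' Tabulate loop motifs by ABEGO string
#'
#' One row per distinct (loop length, loop ABEGO string): total count,
#' per-handedness counts, the handedness ratio max(L/R, R/L) (infinite
#' when one handedness is absent: a motif of exclusively one handedness
#' is maximally biased), the median phi_HH, the frequency within the
#' motif's loop-length class, and the representative fragment id (the
#' fragment whose phi_HH is nearest the class median).
#'
#' @param fragments list of `hlh_fragment`, or a precomputed geometry
#'   table.
#' @return data.frame sorted by loop length then descending count.
#' @export
tabulate_motifs <- function(fragments) {
  geom <- if (is.data.frame(fragments)) fragments else fragment_geometry_table(fragments)
  if (nrow(geom) == 0L) {
    return(data.frame(loop_abego = character(), loop_length = integer(),
                      count = integer(), count_L = integer(),
                      count_R = integer(), handedness_ratio = numeric(),
                      median_phi_HH = numeric(), frequency = numeric(),
                      representative = character(), stringsAsFactors = FALSE))
  }
  key <- split(geom, list(geom$loop_length, geom$loop_abego), drop = TRUE)
  rows <- lapply(key, function(g) {
    nl <- sum(g$handedness == "L")
    nr <- sum(g$handedness == "R")
    ratio <- if (nl == 0L || nr == 0L) Inf else max(nl / nr, nr / nl)
    med <- stats::median(g$phi_HH)
    rep_id <- select_representative_id(g)
    data.frame(loop_abego = g$loop_abego[1L], loop_length = g$loop_length[1L],
               count = nrow(g), count_L = nl, count_R = nr,
               handedness_ratio = ratio, median_phi_HH = med,
               frequency = NA_real_, representative = rep_id,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  for (len in unique(tab$loop_length)) {
    sel <- tab$loop_length == len
    tab$frequency[sel] <- tab$count[sel] / sum(tab$count[sel])
  }
  tab <- tab[order(tab$loop_length, -tab$count, tab$loop_abego), ]
  rownames(tab) <- NULL
  tab
}

# Fragment id nearest the median phi_HH; ties broken by lowest id.
select_representative_id <- function(geom) {
  med <- stats::median(geom$phi_HH)
  d <- abs(geom$phi_HH - med)
  cand <- geom$id[d == min(d)]
  sort(cand)[1L]
}

#' Select handedness-determining motifs per loop-length class
#'
#' Within each loop-length class, the most populated motif among those
#' whose handedness ratio strictly exceeds `min_ratio` is selected;
#' classes where no motif qualifies contribute nothing (motifs with
#' broadly distributed handedness, such as BAB, are thereby excluded).
#'
#' @param stats a [tabulate_motifs()] table.
#' @param min_ratio ratio threshold (default 5.0, strict).
#' @return subset of `stats`, one row per qualifying class.
#' @export
select_motifs <- function(stats, min_ratio = 5.0) {
  ok <- stats[stats$handedness_ratio > min_ratio, , drop = FALSE]
  if (nrow(ok) == 0L) return(ok)
  picked <- lapply(split(ok, ok$loop_length), function(g) {
    g <- g[order(-g$count, g$loop_abego), , drop = FALSE]
    g[1L, , drop = FALSE]
  })
  out <- do.call(rbind, picked)
  rownames(out) <- NULL
  out
}

#' Representative fragment of a motif class
#'
#' Returns the fragment whose phi_HH lies nearest the median of the
#' class distribution (deterministic tie-break: lowest id).
#'
#' @param fragments list of `hlh_fragment`.
#' @param loop_abego the motif's ABEGO string.
#' @param geometry optional precomputed geometry table.
#' @return the representative `hlh_fragment`.
#' @export
select_representative <- function(fragments, loop_abego, geometry = NULL) {
  if (is.null(geometry)) geometry <- fragment_geometry_table(fragments)
  g <- geometry[geometry$loop_abego == loop_abego, , drop = FALSE]
  if (nrow(g) == 0L) stop("no fragments in motif class '", loop_abego, "'")
  id <- select_representative_id(g)
  fragments[[match(id, vapply(fragments, `[[`, "", "id"))]]
}
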