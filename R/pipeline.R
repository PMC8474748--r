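# Umbrella pipeline: extract -> ABEGO -> prune -> theta filter ->
# tabulate -> select motifs -> representatives -> second-helix scans.

#' Pipeline configuration
#'
#' Defaults are the thresholds used throughout the analysis:
#' theta_HH < 60 degrees, handedness ratio > 5.0, TM > 0.55, minimum
#' helix length 10, maximum loop length 10, H scanned over 5..20.
#'
#' @param theta_max hairpin crossing-angle cut (degrees, strict).
#' @param min_ratio handedness-ratio cut (strict).
#' @param tm_threshold folded TM-score cut (strict).
#' @param min_helix minimum helix length kept (residues).
#' @param max_loop maximum loop length kept (residues).
#' @param h_range second-helix lengths scanned.
#' @param variant reference radius variant used in scans.
#' @param n_trajectories builds per scanned H.
#' @param mode "representative" or "sampled" backbone building.
#' @param scan whether to run the second-helix scans.
#' @param seed RNG seed for sampled-mode stages.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(theta_max = 60, min_ratio = 5.0,
                            tm_threshold = 0.55, min_helix = 10,
                            max_loop = 10, h_range = 5:20, variant = 0.75,
                            n_trajectories = 1, mode = "representative",
                            scan = TRUE, seed = 1) {
  structure(list(theta_max = theta_max, min_ratio = min_ratio,
                 tm_threshold = tm_threshold, min_helix = min_helix,
                 max_loop = max_loop, h_range = h_range, variant = variant,
                 n_trajectories = n_trajectories, mode = mode, scan = scan,
                 seed = seed),
            class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full hairpin-to-bundle pipeline
#'
#' Input is either a `synthetic_spec` (fragments are generated) or a
#' list of `list(chain = <backbone_chain>, ss = <track or NULL>)`
#' entries (fragments are extracted; a missing ss track falls back to
#' ABEGO-based helix assignment). Fragments are pruned (terminal A),
#' filtered on theta_HH, tabulated into motifs; per loop-length class
#' the most populated strongly-handed motif is selected, its
#' representative extracted, and (optionally) a second-helix scan run
#' with that motif as both loops.
#'
#' @param input a `synthetic_spec` or list of chain entries.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory; when given, fragment and
#'   motif tables (TSV), scan tables (TSV), representative structures
#'   (PDB) and a JSON run manifest are written.
#' @return list with `fragments`, `geometry`, `motifs`, `selected`,
#'   `representatives`, `scans`, `counts`, `manifest`.
#' @export
run_pipeline <- function(input, config = pipeline_config(), out_dir = NULL) {
  set.seed(config$seed)
  if (inherits(input, "synthetic_spec")) {
    ds <- generate_fragment_dataset(input)
    fragments <- ds$fragments
  } else {
    fragments <- list()
    for (entry in input) {
      ss <- entry$ss
      if (is.null(ss)) ss <- assign_ss_from_abego(entry$chain)
      fragments <- c(fragments,
                     extract_hlh_fragments(entry$chain, ss,
                                           max_loop = config$max_loop,
                                           min_helix = config$min_helix))
    }
  }
  counts <- list(extracted = length(fragments))
  fragments <- prune_terminal_a(fragments)
  counts$after_terminal_A_prune <- length(fragments)
  geometry <- fragment_geometry_table(fragments)
  keep <- geometry$theta_HH < config$theta_max
  fragments <- fragments[keep]
  geometry <- geometry[keep, , drop = FALSE]
  counts$after_theta_filter <- length(fragments)
  motifs <- tabulate_motifs(geometry)
  selected <- select_motifs(motifs, min_ratio = config$min_ratio)
  counts$selected_motifs <- nrow(selected)
  representatives <- lapply(selected$loop_abego, function(m) {
    select_representative(fragments, m, geometry = geometry)
  })
  names(representatives) <- selected$loop_abego
  scans <- list()
  if (isTRUE(config$scan) && nrow(selected) > 0L) {
    for (m in selected$loop_abego) {
      scans[[m]] <- scan_second_helix(
        loop1 = m, loop2 = m, h_range = config$h_range,
        n_trajectories = config$n_trajectories, mode = config$mode,
        threshold = config$tm_threshold, variant = config$variant)
    }
  }
  manifest <- list(
    package = "bundlefold",
    version = as.character(utils::packageVersion("bundlefold")),
    config = config[seq_along(config)],
    counts = counts
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(geometry, file.path(out_dir, "fragments.tsv"))
    write_tsv(motifs, file.path(out_dir, "motifs.tsv"))
    write_tsv(selected, file.path(out_dir, "selected_motifs.tsv"))
    for (m in names(scans)) {
      write_tsv(scans[[m]], file.path(out_dir, sprintf("scan_%s.tsv", m)))
    }
    for (m in names(representatives)) {
      write_backbone_pdb(representatives[[m]]$chain,
                         file.path(out_dir, sprintf("representative_%s.pdb", m)))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(fragments = fragments, geometry = geometry, motifs = motifs,
       selected = selected, representatives = representatives,
       scans = scans, counts = counts, manifest = manifest)
}

#' Shipped representative hairpin fragment of a motif
#'
#' Builds the motif's representative conformer (ideal 14-residue
#' helices, shipped loop torsions) as an `hlh_fragment`.
#'
#' @param motif one of the shipped motif strings ("GB", "GBB", "BAAB",
#'   "BAB").
#' @param handedness "L", "R" or NULL for the motif's majority.
#' @param helix_length flanking helix length (default 14).
#' @return an `hlh_fragment`.
#' @export
representative_hairpin <- function(motif, handedness = NULL,
                                   helix_length = 14) {
  lt <- loop_torsions(motif, mode = "representative", handedness = handedness)
  nl <- nrow(lt)
  l1 <- helix_length
  n <- 2L * l1 + nl
  ideal <- ideal_helix_dihedrals()
  d <- data.frame(phi = rep(ideal[["phi"]], n), psi = rep(ideal[["psi"]], n),
                  omega = 180)
  idx <- (l1 + 1L):(l1 + nl)
  d$phi[idx] <- lt$phi
  d$psi[idx] <- lt$psi
  chain <- build_backbone(d, id = paste0("rep_", motif))
  hlh_fragment(chain, 1:l1, idx, (l1 + nl + 1L):n,
               id = paste0("rep_", motif), source = "shipped")
}
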