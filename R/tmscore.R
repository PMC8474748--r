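# Template-modeling score between equal-topology Calpha structures.
#
# TM = (1/L_ref) * sum_i 1 / (1 + (d_i/d0)^2), with
# d0 = max(0.5, 1.24 * (L_ref - 15)^(1/3) - 1.8), maximized over rigid
# superpositions. The correspondence between model and reference
# residues is fixed by the caller (structures compared here are
# equal-topology by construction), so no alignment search is involved;
# the superposition is found by the standard deterministic
# seed-fragment extension heuristic.

#' TM-score distance scale d0
#' @param l_ref reference length (residues).
#' @return d0 in Angstroms (floored at 0.5).
#' @export
tm_d0 <- function(l_ref) {
  if (l_ref <= 15) return(0.5)
  max(0.5, 1.24 * (l_ref - 15)^(1 / 3) - 1.8)
}

tm_partial <- function(d, d0) 1 / (1 + (d / d0)^2)

#' TM-score of a model against a reference
#'
#' @param model,reference m x 3 Calpha matrices (or `backbone_chain`s).
#' @param correspondence two-column integer matrix mapping model rows
#'   (column 1) to reference rows (column 2); default: identity map
#'   (requires equal lengths).
#' @param l_ref normalization length; defaults to the reference length.
#' @return list of class `tm_result`: `score`, `d0`, `rotation`,
#'   `translation` (model -> reference frame), `distances`
#'   (per-corresponded-pair, Angstroms).
#' @export
tm_score <- function(model, reference, correspondence = NULL, l_ref = NULL) {
  if (inherits(model, "backbone_chain")) model <- model$CA
  if (inherits(reference, "backbone_chain")) reference <- reference$CA
  model <- as.matrix(model); reference <- as.matrix(reference)
  if (is.null(correspondence)) {
    if (nrow(model) != nrow(reference)) {
      stop("identity correspondence requires equal lengths")
    }
    correspondence <- cbind(seq_len(nrow(model)), seq_len(nrow(reference)))
  }
  correspondence <- as.matrix(correspondence)
  if (ncol(correspondence) != 2L || nrow(correspondence) == 0L) {
    stop("correspondence must be a non-empty two-column index matrix")
  }
  if (max(correspondence[, 1L]) > nrow(model) ||
      max(correspondence[, 2L]) > nrow(reference) ||
      min(correspondence) < 1L) {
    stop("correspondence indices out of range")
  }
  if (is.null(l_ref)) l_ref <- nrow(reference)
  if (l_ref < 10L) stop("reference too short for a meaningful TM-score")
  P <- model[correspondence[, 1L], , drop = FALSE]
  Q <- reference[correspondence[, 2L], , drop = FALSE]
  la <- nrow(P)
  d0 <- tm_d0(l_ref)
  seed_lens <- unique(pmax(4L, floor(la / c(1L, 2L, 4L, 8L))))
  cutoffs <- unique(c(d0, d0 + 1.5, d0 + 3))
  best <- list(score = -Inf)
  for (len in seed_lens) {
    starts <- unique(c(seq(1L, la - len + 1L, by = 3L), la - len + 1L))
    for (s in starts) {
      w <- s:(s + len - 1L)
      for (cutoff in cutoffs) {
        sel <- w
        for (iter in 1:30) {
          fit <- kabsch_superpose(P[sel, , drop = FALSE],
                                  Q[sel, , drop = FALSE])
          moved <- apply_transform(P, fit$rotation, fit$translation)
          d <- sqrt(rowSums((moved - Q)^2))
          score <- sum(tm_partial(d, d0)) / l_ref
          if (score > best$score) {
            best <- list(score = score, d0 = d0, rotation = fit$rotation,
                         translation = fit$translation, distances = d)
          }
          dcut <- cutoff
          repeat {
            new_sel <- which(d < dcut)
            if (length(new_sel) >= 4L) break
            dcut <- dcut + 0.5
          }
          if (identical(new_sel, sel)) break
          sel <- new_sel
        }
      }
    }
  }
  structure(best, class = "tm_result")
}

#' @export
print.tm_result <- function(x, ...) {
  cat(sprintf("<tm_result: score %.4f (d0 = %.3f A)>\n", x$score, x$d0))
  invisible(x)
}

#' TM-score with per-helix register freedom
#'
#' The fixed index correspondence cannot absorb the helical register of
#' a built model (one residue of offset rotates a helix's Calpha spiral
#' by ~100 degrees), which a sequence-independent structure alignment
#' would. This variant maximizes the TM-score over integer per-helix
#' register shifts of the correspondence (loops stay excluded),
#' pre-screening shift combinations with a cheap rigid-fit RMSD and
#' evaluating the full superposition search only on the best few. It is
#' deterministic.
#'
#' @param model,reference Calpha matrices (or `backbone_chain`s).
#' @param model_helices,ref_helices lists of integer row-index vectors,
#'   one per helix (same number of helices, pairwise compatible
#'   lengths).
#' @param l_ref normalization length (default: reference length).
#' @param max_shift maximum register shift per helix (default 3).
#' @param top number of pre-screened shift combinations to score fully.
#' @return the best `tm_result`, with the winning shifts in `$shifts`.
#' @export
tm_score_registered <- function(model, reference, model_helices, ref_helices,
                                l_ref = NULL, max_shift = 3, top = 6) {
  if (inherits(model, "backbone_chain")) model <- model$CA
  if (inherits(reference, "backbone_chain")) reference <- reference$CA
  if (length(model_helices) != length(ref_helices)) {
    stop("model and reference must have the same number of helices")
  }
  if (is.null(l_ref)) l_ref <- nrow(reference)
  nh <- length(model_helices)
  shift_rows <- function(mi, ri, s) {
    n <- min(length(mi), length(ri))
    mi <- mi[seq_len(n)]; ri <- ri[seq_len(n)]
    if (s >= 0) cbind(mi[(1 + s):n], ri[1:(n - s)])
    else cbind(mi[1:(n + s)], ri[(1 - s):n])
  }
  grid <- expand.grid(rep(list(-max_shift:max_shift), nh))
  rmsds <- apply(grid, 1L, function(sh) {
    corr <- do.call(rbind, lapply(seq_len(nh), function(h) {
      shift_rows(model_helices[[h]], ref_helices[[h]], sh[h])
    }))
    kabsch_superpose(model[corr[, 1L], , drop = FALSE],
                     reference[corr[, 2L], , drop = FALSE])$rmsd
  })
  keep <- order(rmsds)[seq_len(min(top, nrow(grid)))]
  zero <- which(rowSums(abs(grid)) == 0)
  keep <- unique(c(keep, zero))
  best <- NULL
  for (k in keep) {
    sh <- as.integer(grid[k, ])
    corr <- do.call(rbind, lapply(seq_len(nh), function(h) {
      shift_rows(model_helices[[h]], ref_helices[[h]], sh[h])
    }))
    res <- tm_score(model, reference, corr, l_ref = l_ref)
    if (is.null(best) || res$score > best$score) {
      best <- res
      best$shifts <- sh
    }
  }
  best
}

#' Fraction of conformations counted as folded
#'
#' A conformation is folded when its TM-score is strictly greater than
#' the threshold.
#'
#' @param scores numeric vector of TM-scores in (0, 1].
#' @param threshold folded cut-off (default 0.55).
#' @return fraction in [0, 1].
#' @export
count_folded <- function(scores, threshold = 0.55) {
  if (length(scores) == 0L) stop("cannot compute a folded fraction of zero scores")
  mean(scores > threshold)
}
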