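# Conformational diversity of a target: all-pairs Calpha-RMSD over its
# conformers and selection of the maximally distant pair.

conformer_label <- function(s) paste0(s$structure_id, "_m", s$model_number)

new_conformer_pair <- function(target_id, a, b, scores,
                               cause = "UNKNOWN") {
  la <- conformer_label(a)
  lb <- conformer_label(b)
  if (la > lb) {
    tmp <- a; a <- b; b <- tmp
  }
  structure(list(target_id = target_id, conformer_a = a, conformer_b = b,
                 scores_ab = scores, cause = cause),
            class = "ConformerPair")
}

#' @export
print.ConformerPair <- function(x, ...) {
  cat(sprintf("ConformerPair %s: %s vs %s, RMSD %.3f A (cause %s)\n",
              x$target_id, conformer_label(x$conformer_a),
              conformer_label(x$conformer_b), x$scores_ab$rmsd, x$cause))
  invisible(x)
}

#' Select the maximally distant conformer pair of a target
#'
#' Computes all pairwise Calpha-RMSDs among the conformers (same sequence,
#' matched by residue number) and returns the pair with maximal RMSD, the
#' pair that represents the maximum conformational diversity observed for
#' the protein. Ties break lexicographically by conformer labels. No
#' significance filtering is applied at this stage.
#'
#' @param conformers list of >= 2 `CalphaStructure` objects.
#' @param target_id identifier for the protein; default taken from the
#'   first conformer.
#' @param cause optional diversity-cause annotation
#'   (`LIGAND`/`PTM`/`OLIGOMER`/`NMR`/`UNKNOWN`), supplied as metadata.
#' @return a `ConformerPair` with full `SimilarityScores` for the
#'   selected pair.
#' @export
select_max_diverse_pair <- function(conformers, target_id = NULL,
                                    cause = "UNKNOWN") {
  if (length(conformers) < 2) stop("need at least 2 conformers")
  if (is.null(target_id)) target_id <- conformers[[1]]$structure_id
  labels <- vapply(conformers, conformer_label, character(1))
  ord <- order(labels)
  conformers <- conformers[ord]
  labels <- labels[ord]
  n <- length(conformers)
  best <- NULL
  best_rmsd <- -Inf
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      corr <- build_correspondence(conformers[[i]], conformers[[j]])
      ac <- aligned_coords(conformers[[i]], conformers[[j]], corr)
      r <- cpp_rmsd(ac$model, ac$reference)
      if (r > best_rmsd + 1e-12) {
        best_rmsd <- r
        best <- c(i, j)
      }
    }
  }
  a <- conformers[[best[1]]]
  b <- conformers[[best[2]]]
  scores <- score_pair(a, b)
  new_conformer_pair(target_id, a, b, scores, cause)
}

#' Summary table of conformational diversity over targets
#'
#' Per-group count and RMSD/GDT_TS/TM-score summaries of the selected
#' maximally distant pairs, optionally with the mean summed rASA
#' difference between conformers.
#'
#' @param pairs list of `ConformerPair` objects.
#' @param group_by `"cause"` or `"method"` (experimental method of
#'   conformer A).
#' @param with_rasa compute mean delta-rASA per group (slower).
#' @return data.frame with one row per group.
#' @export
diversity_summary <- function(pairs, group_by = c("cause", "method"),
                              with_rasa = FALSE) {
  group_by <- match.arg(group_by)
  if (!length(pairs)) stop("empty pair list")
  g <- vapply(pairs, function(p) {
    if (group_by == "cause") p$cause else p$conformer_a$method
  }, character(1))
  rmsd <- vapply(pairs, function(p) p$scores_ab$rmsd, numeric(1))
  gdt <- vapply(pairs, function(p) p$scores_ab$gdt_ts, numeric(1))
  tm <- vapply(pairs, function(p) p$scores_ab$tm_score, numeric(1))
  drasa <- if (with_rasa)
    vapply(pairs, function(p) delta_rasa(p$conformer_a, p$conformer_b),
           numeric(1)) else rep(NA_real_, length(pairs))
  out <- do.call(rbind, lapply(split(seq_along(pairs), g), function(i) {
    data.frame(group = g[i[1]], n = length(i),
               rmsd_mean = mean(rmsd[i]), rmsd_max = max(rmsd[i]),
               rmsd_min = min(rmsd[i]), gdt_ts_mean = mean(gdt[i]),
               tm_mean = mean(tm[i]),
               delta_rasa_mean = if (with_rasa) mean(drasa[i]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
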