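# Superposition and the three similarity measures: Calpha-RMSD, GDT_TS,
# TM-score. GDT_TS and TM-score normalize by the reference (conformer)
# length, so partial decoy coverage penalizes scores; RMSD is computed over
# aligned pairs only.

GDT_THRESHOLDS <- c(1, 2, 4, 8)

#' Optimal rigid-body (Kabsch) superposition
#'
#' Least-squares superposition of `model_coords` onto `reference_coords`,
#' rows in correspondence order. The returned rotation is proper
#' (determinant +1); a model point `x` maps to `rotation %*% x +
#' translation`.
#'
#' @param model_coords,reference_coords n x 3 coordinate matrices
#'   (Angstrom), n >= 3.
#' @return list with `rotation` (3 x 3), `translation` (length 3) and
#'   `rmsd` (Angstrom), the global minimum over all rigid transforms.
#' @export
kabsch_superpose <- function(model_coords, reference_coords) {
  model_coords <- as.matrix(model_coords)
  reference_coords <- as.matrix(reference_coords)
  if (nrow(model_coords) < 3) stop("insufficient points: need n >= 3")
  res <- cpp_kabsch(model_coords, reference_coords)
  res$translation <- as.numeric(res$translation)
  res
}

#' TM-score distance scale d0
#'
#' `d0 = 1.24 * (L - 15)^(1/3) - 1.8`, clamped below at 0.5 (for L < 21
#' the raw formula is non-positive).
#'
#' @param l_ref reference length.
#' @return d0 in Angstrom.
#' @export
tm_d0 <- function(l_ref) {
  d0 <- 1.24 * sign(l_ref - 15) * abs(l_ref - 15)^(1 / 3) - 1.8
  max(d0, 0.5)
}

#' Default significance predicate for a comparison
#'
#' Stand-in for an alignment-significance filter (the E-value statistic of
#' the original alignment program is not reproducible here): a comparison
#' is significant when at least `min_aligned` residues align and coverage
#' of the reference is at least `min_coverage`.
#'
#' @param scores a `SimilarityScores` list.
#' @param min_aligned,min_coverage thresholds (defaults 30 and 0.8).
#' @return logical.
#' @export
default_significance <- function(scores, min_aligned = 30,
                                 min_coverage = 0.8) {
  scores$n_aligned >= min_aligned && scores$coverage >= min_coverage
}

#' Apply a significance gate to a comparison
#'
#' Stores the predicate's verdict in `scores$significant`. RMSD-based
#' rankings and rank correlations downstream use only comparisons passing
#' the gate.
#'
#' @param scores a `SimilarityScores` list.
#' @param predicate function of `scores` returning logical; default
#'   [default_significance()].
#' @return `scores` with `significant` set.
#' @export
significance_gate <- function(scores, predicate = default_significance) {
  scores$significant <- isTRUE(predicate(scores))
  scores
}

new_similarity_scores <- function(rmsd, gdt_ts, tm_score, n_aligned,
                                  coverage, significant = NA) {
  structure(list(rmsd = rmsd, gdt_ts = gdt_ts, tm_score = tm_score,
                 n_aligned = as.integer(n_aligned), coverage = coverage,
                 significant = significant),
            class = "SimilarityScores")
}

#' @export
print.SimilarityScores <- function(x, ...) {
  cat(sprintf(
    "SimilarityScores: RMSD %.3f A, GDT_TS %.4f, TM %.4f (n_aligned %d, coverage %.2f, significant %s)\n",
    x$rmsd, x$gdt_ts, x$tm_score, x$n_aligned, x$coverage, x$significant))
  invisible(x)
}

#' All similarity scores for one (model, reference) comparison
#'
#' Computes the Calpha-RMSD over aligned pairs after global superposition
#' and runs the fragment-seeded searches for GDT_TS and TM-score (both
#' normalized by the full reference length), then applies the significance
#' gate.
#'
#' @param model,reference `CalphaStructure` objects.
#' @param corr optional precomputed [build_correspondence()].
#' @param predicate significance predicate, see [significance_gate()].
#' @param metrics measures to compute; dropping `"GDT_TS"` and `"TM"`
#'   skips their superposition searches (the corresponding fields are
#'   `NA`), which is much faster for RMSD-only rankings.
#' @return a `SimilarityScores` list.
#' @export
score_pair <- function(model, reference, corr = NULL,
                       predicate = default_significance,
                       metrics = c("RMSD", "GDT_TS", "TM")) {
  if (is.null(corr)) corr <- build_correspondence(model, reference)
  if (nrow(corr$pairs) < 3)
    stop("fewer than 3 aligned residues between ", model$structure_id,
         " and ", reference$structure_id)
  ac <- aligned_coords(model, reference, corr)
  if (any(c("GDT_TS", "TM") %in% metrics)) {
    res <- cpp_pair_scores(ac$model, ac$reference, corr$n_reference,
                           tm_d0(corr$n_reference), GDT_THRESHOLDS)
    gdt <- if ("GDT_TS" %in% metrics) mean(res$gdt_fractions) else NA_real_
    tm <- if ("TM" %in% metrics) res$tm else NA_real_
    rmsd <- res$rmsd
  } else {
    rmsd <- cpp_rmsd(ac$model, ac$reference)
    gdt <- NA_real_
    tm <- NA_real_
  }
  sc <- new_similarity_scores(
    rmsd = rmsd, gdt_ts = gdt, tm_score = tm,
    n_aligned = nrow(corr$pairs),
    coverage = nrow(corr$pairs) / corr$n_reference
  )
  significance_gate(sc, predicate)
}

#' Global Distance Test Total Score
#'
#' `GDT_TS = (P1 + P2 + P4 + P8) / 4` where `Pd` is the largest fraction
#' of reference residues that fits under `d` Angstrom in any superposition
#' found by a fragment-seeded iterative-inclusion search (sliding seed
#' windows of length 3-7, iterate superpose/include to convergence, keep
#' the largest subset; ties keep the lower-RMSD subset). Fractions use the
#' full reference length as denominator. On small cases the search matches
#' an exhaustive subset oracle; on large cases values are lower bounds of
#' the true maximum.
#'
#' @inheritParams score_pair
#' @return GDT_TS fraction in \[0, 1\].
#' @export
gdt_ts <- function(model, reference, corr = NULL) {
  if (is.null(corr)) corr <- build_correspondence(model, reference)
  if (nrow(corr$pairs) < 3) stop("fewer than 3 aligned residues")
  ac <- aligned_coords(model, reference, corr)
  res <- cpp_pair_scores(ac$model, ac$reference, corr$n_reference,
                         tm_d0(corr$n_reference), GDT_THRESHOLDS)
  mean(res$gdt_fractions)
}

#' TM-score
#'
#' `TM = max over superpositions of (1/L_ref) * sum_i 1/(1 + (d_i/d0)^2)`
#' with `d0` from [tm_d0()]. The search reuses the fragment-seeded
#' iterative scheme of [gdt_ts()] with the TM sum as objective, plus an
#' iteratively-reweighted local refinement of the best superposition.
#'
#' @inheritParams score_pair
#' @return TM-score in (0, 1\].
#' @export
tm_score <- function(model, reference, corr = NULL) {
  if (is.null(corr)) corr <- build_correspondence(model, reference)
  if (nrow(corr$pairs) < 3) stop("fewer than 3 aligned residues")
  ac <- aligned_coords(model, reference, corr)
  res <- cpp_pair_scores(ac$model, ac$reference, corr$n_reference,
                         tm_d0(corr$n_reference), GDT_THRESHOLDS)
  res$tm
}

#' Per-position deviation and z-score profile
#'
#' Distances `d_i` are Calpha-Calpha distances at aligned positions after
#' one global Kabsch superposition over all aligned positions;
#' `z_i = (d_i - mean(d)) / sd(d)`. When `sd(d) = 0` (identical
#' structures) all z are set to 0 so the profile stays finite and flat.
#'
#' @inheritParams score_pair
#' @return list with `positions` (reference residue numbers), `d`
#'   (Angstrom) and `z`.
#' @export
per_position_profile <- function(model, reference, corr = NULL) {
  if (is.null(corr)) corr <- build_correspondence(model, reference)
  if (nrow(corr$pairs) < 3) stop("fewer than 3 aligned residues")
  ac <- aligned_coords(model, reference, corr)
  k <- cpp_kabsch(ac$model, ac$reference)
  moved <- ac$model %*% t(k$rotation)
  moved <- sweep(moved, 2, -as.numeric(k$translation))
  d <- sqrt(rowSums((moved - ac$reference)^2))
  s <- sd(d)
  # sd below coordinate precision counts as zero (identical structures)
  z <- if (is.na(s) || s < 1e-9) rep(0, length(d)) else (d - mean(d)) / s
  list(positions = reference$resno[corr$pairs[, 2]], d = d, z = z)
}
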