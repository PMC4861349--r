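# Core decoy assessment: filtering, ranking against both conformers,
# rank correlation, best-decoy selection and cross-comparison, and the
# one-vs-two-best-decoy classification of each target.

#' Construct a decoy record
#'
#' @param decoy_id unique decoy name within the target.
#' @param structure `CalphaStructure` of the decoy.
#' @param group_label dataset of origin (e.g. generator name).
#' @param true_source optional ground-truth label for synthetic decoys
#'   (`"A"` or `"B"`).
#' @return object of class `DecoyRecord`.
#' @export
decoy_record <- function(decoy_id, structure, group_label = "decoys",
                         true_source = NA_character_) {
  structure(list(decoy_id = as.character(decoy_id), structure = structure,
                 group_label = group_label, true_source = true_source,
                 passed_filters = NA, scores_a = NULL, scores_b = NULL),
            class = "DecoyRecord")
}

#' Filter decoys on coverage and missing-run length
#'
#' A decoy is kept when its coverage of the target numbering is at least
#' `min_coverage` and its longest run of consecutive missing reference
#' residues is at most `max_missing_run` (boundaries inclusive: 0.80 and a
#' run of exactly 5 pass). Decoys whose correspondence cannot be built
#' fail the filters.
#'
#' @param decoys list of `DecoyRecord`.
#' @param reference target `CalphaStructure` providing the numbering.
#' @param min_coverage,max_missing_run thresholds (defaults 0.8 and 5).
#' @return the list with `passed_filters` set on every record.
#' @export
filter_decoys <- function(decoys, reference, min_coverage = 0.8,
                          max_missing_run = 5L) {
  lapply(decoys, function(d) {
    cov <- tryCatch(coverage(d$structure, reference), error = function(e) NULL)
    d$passed_filters <- !is.null(cov) &&
      cov$coverage >= min_coverage &&
      cov$max_consecutive_missing <= max_missing_run
    d
  })
}

#' Rank decoys under one similarity measure
#'
#' RMSD ranks ascending (best = smallest); GDT_TS and TM ranks descending
#' (best = largest). Exact score ties receive average ranks.
#'
#' @param scores named numeric vector of decoy scores (names = decoy ids).
#' @param metric one of `"RMSD"`, `"GDT_TS"`, `"TM"`.
#' @return data.frame with `decoy_id`, `score`, `rank`, ordered best
#'   first (ties by decoy id).
#' @export
rank_decoys <- function(scores, metric = c("RMSD", "GDT_TS", "TM")) {
  metric <- match.arg(metric)
  if (!length(scores)) stop("no scored decoys to rank")
  key <- if (metric == "RMSD") scores else -scores
  rk <- rank(key, ties.method = "average")
  out <- data.frame(decoy_id = names(scores), score = unname(scores),
                    rank = unname(rk), stringsAsFactors = FALSE)
  out[order(out$rank, out$decoy_id), , drop = FALSE]
}

#' Spearman rank correlation of two decoy rankings
#'
#' Tie-robust form: the Pearson product-moment correlation of the two
#' average-rank vectors, computed over the decoys present in both
#' rankings (re-ranked within the intersection). Fewer than 3 shared
#' decoys is undefined and returns `NA`.
#'
#' @param ranking_a,ranking_b data.frames from [rank_decoys()].
#' @return value in \[-1, 1\] or `NA`.
#' @export
spearman_rho <- function(ranking_a, ranking_b) {
  shared <- intersect(ranking_a$decoy_id, ranking_b$decoy_id)
  if (length(shared) < 3) return(NA_real_)
  sa <- ranking_a$score[match(shared, ranking_a$decoy_id)]
  sb <- ranking_b$score[match(shared, ranking_b$decoy_id)]
  ra <- rank(sa, ties.method = "average")
  rb <- rank(sb, ties.method = "average")
  if (sd(ra) == 0 || sd(rb) == 0) return(NA_real_)
  cor(ra, rb)
}

metric_score <- function(scores, metric) {
  switch(metric, RMSD = scores$rmsd, GDT_TS = scores$gdt_ts,
         TM = scores$tm_score)
}

#' Assess one target against its conformer pair
#'
#' The full per-target analysis: score every passed decoy against both
#' conformers, rank under each requested measure, correlate the two
#' rankings (Spearman), pick the best decoy per (conformer, measure),
#' cross-compare each best decoy with the alternative conformer, and
#' classify the target `SAME_BEST` (both conformers select the same best
#' decoy) or `DIFFERENT_BEST`. RMSD-based rankings keep only comparisons
#' passing the significance gate; the RMSD rank correlation uses decoys
#' significant against both conformers. Best-decoy ties break
#' deterministically by decoy id.
#'
#' @param pair `ConformerPair` of the target.
#' @param decoys list of `DecoyRecord` (filters are applied if not yet).
#' @param metrics subset of `c("RMSD", "GDT_TS", "TM")`.
#' @param min_significant targets with at least this many significant
#'   decoy-conformer comparisons are flagged `high_quality` (default 3).
#' @param predicate significance predicate, see [significance_gate()].
#' @param min_coverage,max_missing_run decoy filter thresholds.
#' @return object of class `TargetAssessment`.
#' @export
assess_target <- function(pair, decoys,
                          metrics = c("RMSD", "GDT_TS", "TM"),
                          min_significant = 3L,
                          predicate = default_significance,
                          min_coverage = 0.8, max_missing_run = 5L) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  a <- pair$conformer_a
  b <- pair$conformer_b
  if (any(is.na(vapply(decoys, function(d) d$passed_filters, logical(1)))))
    decoys <- filter_decoys(decoys, a, min_coverage, max_missing_run)
  passed <- Filter(function(d) isTRUE(d$passed_filters), decoys)
  ids <- vapply(passed, `[[`, character(1), "decoy_id")
  if (anyDuplicated(ids)) stop("duplicated decoy ids")

  score_against <- function(conf) {
    out <- lapply(passed, function(d)
      tryCatch(score_pair(d$structure, conf, predicate = predicate,
                          metrics = metrics),
               error = function(e) NULL))
    names(out) <- ids
    out
  }
  sa <- score_against(a)
  sb <- score_against(b)
  ok <- !vapply(sa, is.null, logical(1)) & !vapply(sb, is.null, logical(1))
  sa <- sa[ok]
  sb <- sb[ok]
  ids <- ids[ok]

  n_sig <- sum(vapply(sa, `[[`, logical(1), "significant")) +
    sum(vapply(sb, `[[`, logical(1), "significant"))

  empty <- structure(list(
    target_id = pair$target_id, pair = pair,
    n_decoys_total = length(decoys), n_decoys_passed = length(ids),
    n_significant = n_sig, high_quality = n_sig >= min_significant,
    spearman_rho = setNames(rep(NA_real_, length(metrics)), metrics),
    best = NULL, classification = setNames(rep(NA_character_,
                                               length(metrics)), metrics),
    rankings = NULL, scores_a = sa, scores_b = sb,
    score_summary = NULL, flagged = length(ids) == 0
  ), class = "TargetAssessment")
  if (!length(ids)) return(empty)

  rankings <- list()
  rho <- setNames(rep(NA_real_, length(metrics)), metrics)
  classification <- setNames(rep(NA_character_, length(metrics)), metrics)
  best_rows <- list()
  for (m in metrics) {
    va <- vapply(sa, metric_score, numeric(1), metric = m)
    vb <- vapply(sb, metric_score, numeric(1), metric = m)
    keep_a <- keep_b <- rep(TRUE, length(ids))
    if (m == "RMSD") {
      keep_a <- vapply(sa, `[[`, logical(1), "significant")
      keep_b <- vapply(sb, `[[`, logical(1), "significant")
    }
    if (!any(keep_a) || !any(keep_b)) next
    ra <- rank_decoys(setNames(va[keep_a], ids[keep_a]), m)
    rb <- rank_decoys(setNames(vb[keep_b], ids[keep_b]), m)
    rankings[[m]] <- list(a = ra, b = rb)
    rho[m] <- spearman_rho(ra, rb)
    best_a <- ra$decoy_id[1]
    best_b <- rb$decoy_id[1]
    classification[m] <- if (identical(best_a, best_b)) "SAME_BEST"
                         else "DIFFERENT_BEST"
    best_rows[[paste(m, "a")]] <- data.frame(
      metric = m, conformer = "a", decoy_id = best_a,
      score = ra$score[1], rmsd_own = sa[[best_a]]$rmsd,
      rmsd_cross = sb[[best_a]]$rmsd, stringsAsFactors = FALSE)
    best_rows[[paste(m, "b")]] <- data.frame(
      metric = m, conformer = "b", decoy_id = best_b,
      score = rb$score[1], rmsd_own = sb[[best_b]]$rmsd,
      rmsd_cross = sa[[best_b]]$rmsd, stringsAsFactors = FALSE)
  }
  best <- if (length(best_rows)) do.call(rbind, best_rows) else NULL
  if (!is.null(best)) rownames(best) <- NULL

  groups <- vapply(passed[ok], `[[`, character(1), "group_label")
  gdt_all <- c(vapply(sa, `[[`, numeric(1), "gdt_ts"),
               vapply(sb, `[[`, numeric(1), "gdt_ts"))
  tm_all <- c(vapply(sa, `[[`, numeric(1), "tm_score"),
              vapply(sb, `[[`, numeric(1), "tm_score"))
  rmsd_all <- c(vapply(sa, `[[`, numeric(1), "rmsd"),
                vapply(sb, `[[`, numeric(1), "rmsd"))
  score_summary <- do.call(rbind, lapply(unique(groups), function(g) {
    idx <- rep(groups == g, 2)
    data.frame(group_label = g, n_decoys = sum(groups == g),
               gdt_min = min(gdt_all[idx]), gdt_avg = mean(gdt_all[idx]),
               tm_min = min(tm_all[idx]), tm_avg = mean(tm_all[idx]),
               rmsd_max = max(rmsd_all[idx]), rmsd_avg = mean(rmsd_all[idx]),
               stringsAsFactors = FALSE)
  }))

  structure(list(
    target_id = pair$target_id, pair = pair,
    n_decoys_total = length(decoys), n_decoys_passed = length(ids),
    n_significant = n_sig, high_quality = n_sig >= min_significant,
    spearman_rho = rho, best = best, classification = classification,
    rankings = rankings, scores_a = sa, scores_b = sb,
    score_summary = score_summary, flagged = FALSE
  ), class = "TargetAssessment")
}

#' @export
print.TargetAssessment <- function(x, ...) {
  cat(sprintf("TargetAssessment %s: %d/%d decoys passed, %d significant%s\n",
              x$target_id, x$n_decoys_passed, x$n_decoys_total,
              x$n_significant,
              if (x$high_quality) " (high quality)" else ""))
  for (m in names(x$classification))
    cat(sprintf("  %-7s rho = %6s  %s\n", m,
                formatC(x$spearman_rho[m], digits = 3, format = "f"),
                x$classification[m]))
  invisible(x)
}

#' Cohort-level report over many target assessments
#'
#' Per measure: the fraction of targets where both conformers select the
#' same best decoy (`SAME_BEST`) vs different ones, the mean Spearman
#' rank correlation, and mean best-decoy RMSD against its own conformer
#' vs cross-compared with the alternative conformer over
#' `DIFFERENT_BEST` targets. Fractions are reported both over all targets
#' and over the high-quality subset. A per-dataset score summary table is
#' attached.
#'
#' @param assessments list of `TargetAssessment`.
#' @return list with `per_metric` (data.frame), `per_group` (data.frame)
#'   and `n_targets` counts.
#' @export
cohort_report <- function(assessments) {
  if (!length(assessments)) stop("no assessments")
  assessments <- Filter(function(a) !isTRUE(a$flagged), assessments)
  metrics <- names(assessments[[1]]$classification)
  hq <- vapply(assessments, `[[`, logical(1), "high_quality")
  per_metric <- do.call(rbind, lapply(metrics, function(m) {
    cls <- vapply(assessments, function(a) a$classification[[m]],
                  character(1))
    rho <- vapply(assessments, function(a) a$spearman_rho[[m]], numeric(1))
    own <- vapply(assessments, function(a) {
      if (is.null(a$best)) return(NA_real_)
      rows <- a$best[a$best$metric == m, , drop = FALSE]
      mean(rows$rmsd_own)
    }, numeric(1))
    cross <- vapply(assessments, function(a) {
      if (is.null(a$best)) return(NA_real_)
      rows <- a$best[a$best$metric == m, , drop = FALSE]
      mean(rows$rmsd_cross)
    }, numeric(1))
    def <- !is.na(cls)
    diffb <- def & cls == "DIFFERENT_BEST"
    sameb <- def & cls == "SAME_BEST"
    data.frame(
      metric = m,
      n_classified = sum(def),
      frac_same_best = if (any(def)) sum(sameb) / sum(def) else NA_real_,
      frac_different_best = if (any(def)) sum(diffb) / sum(def)
                            else NA_real_,
      frac_same_best_hq = if (any(def & hq))
        sum(sameb & hq) / sum(def & hq) else NA_real_,
      mean_spearman = mean(rho, na.rm = TRUE),
      mean_best_rmsd_own_diff = if (any(diffb)) mean(own[diffb])
                                else NA_real_,
      mean_best_rmsd_cross_diff = if (any(diffb)) mean(cross[diffb])
                                  else NA_real_,
      stringsAsFactors = FALSE)
  }))
  summaries <- do.call(rbind, lapply(assessments, `[[`, "score_summary"))
  per_group <- if (is.null(summaries)) NULL else
    do.call(rbind, lapply(split(summaries, summaries$group_label),
                          function(s)
      data.frame(group_label = s$group_label[1],
                 n_targets = nrow(s), n_decoys = sum(s$n_decoys),
                 gdt_min = min(s$gdt_min),
                 gdt_avg = sum(s$gdt_avg * s$n_decoys) / sum(s$n_decoys),
                 tm_min = min(s$tm_min),
                 tm_avg = sum(s$tm_avg * s$n_decoys) / sum(s$n_decoys),
                 rmsd_max = max(s$rmsd_max),
                 rmsd_avg = sum(s$rmsd_avg * s$n_decoys) / sum(s$n_decoys),
                 stringsAsFactors = FALSE)))
  if (!is.null(per_group)) rownames(per_group) <- NULL
  list(per_metric = per_metric, per_group = per_group,
       n_targets = length(assessments), n_high_quality = sum(hq))
}
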