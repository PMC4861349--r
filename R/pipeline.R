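# End-to-end orchestration: manifests in, TSV/JSON report bundle out.
# All tables are written in manifest order with explicit headers so a
# rerun with identical inputs and config is byte-identical.

#' Build a pipeline run configuration
#'
#' @param conformer_manifest TSV with columns `target_id`, `structure_id`,
#'   `path`, `model_number`, `chain`, `cause`.
#' @param decoy_manifest TSV with columns `target_id`, `decoy_id`, `path`,
#'   `chain`, `group_label`.
#' @param out_dir output directory (created if missing).
#' @param metrics measures to compute.
#' @param min_coverage,max_missing_run decoy filter thresholds.
#' @param min_significant high-quality subset rule.
#' @param sig_min_aligned,sig_min_coverage significance predicate
#'   parameters.
#' @param seed integer recorded for provenance (the assessment itself is
#'   deterministic).
#' @return object of class `RunConfig`.
#' @export
run_config <- function(conformer_manifest, decoy_manifest, out_dir,
                       metrics = c("RMSD", "GDT_TS", "TM"),
                       min_coverage = 0.8, max_missing_run = 5L,
                       min_significant = 3L,
                       sig_min_aligned = 30L, sig_min_coverage = 0.8,
                       seed = 1L) {
  structure(list(conformer_manifest = conformer_manifest,
                 decoy_manifest = decoy_manifest, out_dir = out_dir,
                 metrics = metrics, min_coverage = min_coverage,
                 max_missing_run = as.integer(max_missing_run),
                 min_significant = as.integer(min_significant),
                 sig_min_aligned = as.integer(sig_min_aligned),
                 sig_min_coverage = sig_min_coverage,
                 seed = as.integer(seed)),
            class = "RunConfig")
}

read_manifest <- function(path, required) {
  m <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(required, names(m))
  if (length(missing))
    stop("manifest ", path, " lacks columns: ",
         paste(missing, collapse = ", "))
  m
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

config_hash <- function(config) {
  flat <- paste(names(unclass(config)),
                vapply(unclass(config), function(x)
                  paste(format(x, digits = 15), collapse = ","),
                  character(1)),
                sep = "=", collapse = ";")
  # small deterministic polynomial hash; provenance only
  h <- 0
  for (b in utf8ToInt(flat)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

load_conformers <- function(rows) {
  lapply(seq_len(nrow(rows)), function(i) {
    mods <- read_structures(rows$path[i],
                            chain = if (nzchar(rows$chain[i]))
                              rows$chain[i] else NULL,
                            structure_id = rows$structure_id[i])
    want <- as.integer(rows$model_number[i])
    hit <- Filter(function(s) s$model_number == want, mods)
    if (!length(hit))
      stop("model ", want, " not found in ", rows$path[i])
    hit[[1]]
  })
}

comparison_rows <- function(a) {
  if (!length(a$scores_a)) return(NULL)
  row1 <- function(conf, sc, id)
    data.frame(target_id = a$target_id, reference_conformer = conf,
               model_id = id, rmsd = sc$rmsd, gdt_ts = sc$gdt_ts,
               tm_score = sc$tm_score, n_aligned = sc$n_aligned,
               coverage = sc$coverage, significant = sc$significant,
               stringsAsFactors = FALSE)
  rbind(
    do.call(rbind, Map(row1, "a", a$scores_a, names(a$scores_a))),
    do.call(rbind, Map(row1, "b", a$scores_b, names(a$scores_b))))
}

profile_rows <- function(a, decoy_lookup) {
  pair <- a$pair
  rows <- list()
  prof <- per_position_profile(pair$conformer_a, pair$conformer_b)
  rows[["conf"]] <- data.frame(target = a$target_id,
                               comparison = "conformer_a_vs_b",
                               residue_number = prof$positions,
                               d = prof$d, z = prof$z,
                               stringsAsFactors = FALSE)
  if (!is.null(a$best)) {
    bb <- a$best[a$best$metric == "RMSD", , drop = FALSE]
    for (i in seq_len(nrow(bb))) {
      conf <- if (bb$conformer[i] == "a") pair$conformer_a
              else pair$conformer_b
      dec <- decoy_lookup[[bb$decoy_id[i]]]
      if (is.null(dec)) next
      prof <- per_position_profile(dec, conf)
      rows[[paste0("best", i)]] <- data.frame(
        target = a$target_id,
        comparison = paste0("best_decoy_vs_conformer_", bb$conformer[i]),
        residue_number = prof$positions, d = prof$d, z = prof$z,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run the full assessment pipeline
#'
#' Reads the conformer and decoy manifests, and per target (in manifest
#' order): selects the maximally distant conformer pair, filters decoys,
#' scores every decoy against both conformers, ranks and correlates,
#' selects and cross-compares best decoys, classifies the target, and
#' finally writes the report bundle: `pairs.tsv`, `comparisons.tsv`,
#' `assessments.json`, `cohort_metrics.tsv`, `cohort_groups.tsv`,
#' `zprofiles.tsv`, a `schema.tsv` sidecar and `run_log.txt`. Per-target
#' failures are logged and skipped; identical inputs and config give
#' byte-identical outputs.
#'
#' @param config a [run_config()].
#' @return list with `assessments`, `pairs`, `report` (invisible copy of
#'   what was written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  conf_m <- read_manifest(config$conformer_manifest,
                          c("target_id", "structure_id", "path",
                            "model_number", "chain", "cause"))
  dec_m <- read_manifest(config$decoy_manifest,
                         c("target_id", "decoy_id", "path", "chain",
                           "group_label"))
  predicate <- function(s)
    default_significance(s, config$sig_min_aligned,
                         config$sig_min_coverage)
  targets <- unique(conf_m$target_id)
  log_lines <- c(sprintf("conformerQA %s", packageVersion("conformerQA")),
                 sprintf("config_hash %s", config_hash(config)),
                 sprintf("seed %d", config$seed),
                 sprintf("thresholds coverage=%g max_missing_run=%d min_significant=%d sig_min_aligned=%d sig_min_coverage=%g",
                         config$min_coverage, config$max_missing_run,
                         config$min_significant, config$sig_min_aligned,
                         config$sig_min_coverage),
                 sprintf("targets_in %d", length(targets)))
  assessments <- list()
  pair_rows <- list()
  comp_rows <- list()
  prof_rows <- list()
  for (tid in targets) {
    res <- tryCatch({
      crows <- conf_m[conf_m$target_id == tid, , drop = FALSE]
      conformers <- load_conformers(crows)
      cause <- crows$cause[1]
      if (length(conformers) < 2) stop("target needs >= 2 conformers")
      pair <- select_max_diverse_pair(conformers, target_id = tid,
                                      cause = if (nzchar(cause)) cause
                                              else "UNKNOWN")
      drows <- dec_m[dec_m$target_id == tid, , drop = FALSE]
      decoys <- lapply(seq_len(nrow(drows)), function(i) {
        s <- read_structures(drows$path[i],
                             chain = if (nzchar(drows$chain[i]))
                               drows$chain[i] else NULL,
                             structure_id = drows$decoy_id[i])[[1]]
        decoy_record(drows$decoy_id[i], s, drows$group_label[i])
      })
      a <- assess_target(pair, decoys, metrics = config$metrics,
                         min_significant = config$min_significant,
                         predicate = predicate,
                         min_coverage = config$min_coverage,
                         max_missing_run = config$max_missing_run)
      lookup <- setNames(lapply(decoys, `[[`, "structure"),
                         vapply(decoys, `[[`, character(1), "decoy_id"))
      list(a = a, pair = pair, lookup = lookup)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      log_lines <- c(log_lines,
                     sprintf("target %s FAILED: %s", tid,
                             conditionMessage(res)))
      next
    }
    a <- res$a
    assessments[[tid]] <- a
    pair_rows[[tid]] <- data.frame(
      target_id = tid,
      conformer_a = conformer_label(res$pair$conformer_a),
      conformer_b = conformer_label(res$pair$conformer_b),
      rmsd = res$pair$scores_ab$rmsd,
      gdt_ts = res$pair$scores_ab$gdt_ts,
      tm_score = res$pair$scores_ab$tm_score,
      cause = res$pair$cause, stringsAsFactors = FALSE)
    comp_rows[[tid]] <- comparison_rows(a)
    if ("RMSD" %in% config$metrics && !isTRUE(a$flagged))
      prof_rows[[tid]] <- profile_rows(a, res$lookup)
    log_lines <- c(log_lines, sprintf(
      "target %s decoys_total=%d decoys_passed=%d significant=%d",
      tid, a$n_decoys_total, a$n_decoys_passed, a$n_significant))
  }
  if (!length(assessments)) stop("no target could be assessed")
  report <- cohort_report(assessments)

  write_tsv(do.call(rbind, pair_rows),
            file.path(config$out_dir, "pairs.tsv"))
  write_tsv(do.call(rbind, comp_rows),
            file.path(config$out_dir, "comparisons.tsv"))
  write_tsv(report$per_metric,
            file.path(config$out_dir, "cohort_metrics.tsv"))
  if (!is.null(report$per_group))
    write_tsv(report$per_group,
              file.path(config$out_dir, "cohort_groups.tsv"))
  if (length(prof_rows))
    write_tsv(do.call(rbind, prof_rows),
              file.path(config$out_dir, "zprofiles.tsv"))
  json <- lapply(assessments, function(a) list(
    target_id = a$target_id, n_decoys_total = a$n_decoys_total,
    n_decoys_passed = a$n_decoys_passed,
    n_significant = a$n_significant, high_quality = a$high_quality,
    spearman_rho = as.list(a$spearman_rho),
    classification = as.list(a$classification),
    best = a$best))
  jsonlite::write_json(json, file.path(config$out_dir,
                                       "assessments.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  schema <- data.frame(
    file = c("pairs.tsv", "comparisons.tsv", "cohort_metrics.tsv",
             "cohort_groups.tsv", "zprofiles.tsv"),
    units = c("rmsd:Angstrom gdt_ts:[0,1] tm_score:(0,1]",
              "rmsd:Angstrom gdt_ts:[0,1] tm_score:(0,1] coverage:[0,1]",
              "fractions:[0,1] mean_spearman:[-1,1] rmsd:Angstrom",
              "gdt:[0,1] tm:(0,1] rmsd:Angstrom",
              "d:Angstrom z:unitless"),
    stringsAsFactors = FALSE)
  write_tsv(schema, file.path(config$out_dir, "schema.tsv"))
  log_lines <- c(log_lines,
                 sprintf("targets_assessed %d", length(assessments)))
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(list(assessments = assessments,
                 pairs = do.call(rbind, pair_rows), report = report))
}

#' Write a synthetic dataset in the layout the pipeline consumes
#'
#' For each spec: conformer A and B PDB files, one PDB per decoy, and the
#' two manifests (`conformers.tsv`, `decoys.tsv`).
#'
#' @param specs list of [synthetic_target_spec()] (or a single one).
#' @param dir output directory.
#' @return list with the two manifest paths.
#' @export
write_synthetic_dataset <- function(specs, dir) {
  if (inherits(specs, "SyntheticTargetSpec")) specs <- list(specs)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  conf_rows <- list()
  dec_rows <- list()
  for (spec in specs) {
    gen <- sample_decoys(spec)
    tdir <- file.path(dir, spec$target_id)
    dir.create(tdir, showWarnings = FALSE)
    for (side in c("a", "b")) {
      s <- gen$pair[[paste0("conformer_", side)]]
      p <- file.path(tdir, paste0(s$structure_id, ".pdb"))
      write_pdb(s, p)
      conf_rows[[paste0(spec$target_id, side)]] <- data.frame(
        target_id = spec$target_id, structure_id = s$structure_id,
        path = p, model_number = 1L, chain = "A", cause = "UNKNOWN",
        stringsAsFactors = FALSE)
    }
    for (d in gen$decoys) {
      p <- file.path(tdir, paste0(d$decoy_id, ".pdb"))
      write_pdb(d$structure, p)
      dec_rows[[d$decoy_id]] <- data.frame(
        target_id = spec$target_id, decoy_id = d$decoy_id, path = p,
        chain = "A", group_label = d$group_label,
        stringsAsFactors = FALSE)
    }
  }
  cm <- file.path(dir, "conformers.tsv")
  dm <- file.path(dir, "decoys.tsv")
  write_tsv(do.call(rbind, conf_rows), cm)
  write_tsv(do.call(rbind, dec_rows), dm)
  list(conformer_manifest = cm, decoy_manifest = dm)
}
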