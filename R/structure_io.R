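# Reading, writing and aligning Calpha traces from PDB-format files.

AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M", SEC = "U", PYL = "O", UNK = "X"
)
AA1TO3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL", X = "UNK"
)

#' Construct a Calpha trace structure
#'
#' A `CalphaStructure` is one conformer or decoy reduced to its ordered
#' Calpha trace. Residue identity is keyed by residue number plus optional
#' insertion code; insertion codes order after their base number.
#'
#' @param structure_id PDB id or decoy name.
#' @param model_number MODEL record number (>= 1).
#' @param chain_id single chain character.
#' @param resno integer residue numbers.
#' @param aa one-letter amino-acid codes, same length as `resno`.
#' @param xyz numeric matrix of Calpha coordinates (n x 3, Angstrom).
#' @param method one of `"XRD"`, `"NMR"`, `"MODEL"`, `"SYNTHETIC"`.
#' @param ins insertion codes (default empty strings).
#' @return object of class `CalphaStructure`.
#' @export
calpha_structure <- function(structure_id, model_number = 1L, chain_id = "A",
                             resno, aa, xyz,
                             method = c("MODEL", "XRD", "NMR", "SYNTHETIC"),
                             ins = NULL) {
  method <- match.arg(method)
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  n <- length(resno)
  if (n < 1L) stop("empty trace: a structure needs at least one residue")
  if (is.null(ins)) ins <- rep("", n)
  if (length(aa) != n || nrow(xyz) != n || ncol(xyz) != 3L ||
      length(ins) != n)
    stop("resno, aa, ins and xyz rows must agree; xyz must have 3 columns")
  if (any(!is.finite(xyz))) stop("non-finite coordinates")
  key <- paste0(resno, ins)
  ord <- order(resno, ins)
  if (any(duplicated(key))) stop("duplicated residue identifiers")
  if (!identical(ord, seq_len(n)))
    stop("residue numbers must be strictly increasing (insertion codes ",
         "order after their base number)")
  structure(list(structure_id = as.character(structure_id),
                 model_number = as.integer(model_number),
                 chain_id = as.character(chain_id),
                 resno = as.integer(resno), ins = as.character(ins),
                 aa = toupper(as.character(aa)), xyz = xyz,
                 method = method),
            class = "CalphaStructure")
}

#' @export
print.CalphaStructure <- function(x, ...) {
  cat(sprintf("CalphaStructure %s (model %d, chain %s, %s): %d residues, %d-%d\n",
              x$structure_id, x$model_number, x$chain_id, x$method,
              length(x$resno), min(x$resno), max(x$resno)))
  invisible(x)
}

#' @export
length.CalphaStructure <- function(x) length(x$resno)

residue_keys <- function(s) paste0(s$resno, s$ins)

parse_expdta <- function(lines) {
  exp_line <- grep("^EXPDTA", lines, value = TRUE)
  if (!length(exp_line)) return("MODEL")
  txt <- toupper(exp_line[1])
  if (grepl("NMR", txt)) return("NMR")
  if (grepl("X-RAY|XRAY|DIFFRACTION", txt)) return("XRD")
  if (grepl("SYNTHETIC", txt)) return("SYNTHETIC")
  "MODEL"
}

# Parse the fixed-width fields of CA ATOM records in one model's lines.
parse_ca_records <- function(lines, chain, path) {
  atom <- lines[startsWith(lines, "ATOM")]
  if (!length(atom)) stop("empty trace: no ATOM records in ", path)
  name <- trimws(substr(atom, 13, 16))
  atom <- atom[name == "CA"]
  if (!length(atom)) stop("empty trace: no CA atoms in ", path)
  ch <- substr(atom, 22, 22)
  if (is.null(chain)) chain <- ch[1]
  if (!any(ch == chain))
    stop("chain not found: '", chain, "' absent from ", path,
         " (available: ", paste(unique(ch), collapse = ", "), ")")
  atom <- atom[ch == chain]
  df <- data.frame(
    altloc = substr(atom, 17, 17),
    resname = trimws(substr(atom, 18, 20)),
    resno = as.integer(substr(atom, 23, 26)),
    ins = trimws(substr(atom, 27, 27)),
    x = as.numeric(substr(atom, 31, 38)),
    y = as.numeric(substr(atom, 39, 46)),
    z = as.numeric(substr(atom, 47, 54)),
    occ = suppressWarnings(as.numeric(substr(atom, 55, 60))),
    stringsAsFactors = FALSE
  )
  df$occ[is.na(df$occ)] <- 1
  # altloc resolution: highest occupancy wins, ties keep the first record
  key <- paste0(df$resno, "_", df$ins)
  keep <- unlist(lapply(split(seq_len(nrow(df)), factor(key, unique(key))),
                        function(i) i[which.max(df$occ[i])]),
                 use.names = FALSE)
  df <- df[sort(keep), , drop = FALSE]
  df <- df[order(df$resno, df$ins), , drop = FALSE]
  aa <- AA3TO1[df$resname]
  aa[is.na(aa)] <- "X"
  list(df = df, aa = unname(aa), chain = chain)
}

#' Read Calpha traces from a PDB file
#'
#' Multi-model files (NMR ensembles, concatenated decoys) yield one
#' structure per MODEL record; each model is treated as a separate
#' conformer. Only CA atoms of the requested chain are kept; alternate
#' locations resolve to the highest-occupancy record (ties keep the first
#' encountered). The experimental method is read from the EXPDTA record
#' when present, otherwise the structure is labelled `MODEL`.
#'
#' @param path PDB-format file.
#' @param chain chain to extract; default the first chain seen.
#' @param structure_id identifier; default the file name without extension.
#' @return list of [calpha_structure()] objects.
#' @export
read_structures <- function(path, chain = NULL, structure_id = NULL) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (is.null(structure_id))
    structure_id <- tools::file_path_sans_ext(basename(path))
  method <- parse_expdta(lines)
  model_starts <- grep("^MODEL", lines)
  if (!length(model_starts)) {
    blocks <- list(lines)
    model_numbers <- 1L
  } else {
    ends <- c(model_starts[-1] - 1L, length(lines))
    blocks <- Map(function(s, e) lines[s:e], model_starts, ends)
    model_numbers <- suppressWarnings(
      as.integer(substr(lines[model_starts], 11, 14)))
    if (any(is.na(model_numbers))) model_numbers <- seq_along(blocks)
  }
  out <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    p <- parse_ca_records(blocks[[i]], chain, path)
    out[[i]] <- calpha_structure(structure_id, model_numbers[i], p$chain,
                                 p$df$resno, p$aa,
                                 cbind(p$df$x, p$df$y, p$df$z),
                                 method = method, ins = p$df$ins)
  }
  out
}

#' Write Calpha traces to a PDB-format file
#'
#' Writes fixed-width ATOM records (PDB v3.3 columns); a list of several
#' structures is wrapped in MODEL/ENDMDL records. Coordinates are written
#' with 3 decimal places, the PDB precision.
#'
#' @param structures a `CalphaStructure` or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structures, path) {
  if (inherits(structures, "CalphaStructure")) structures <- list(structures)
  method_line <- switch(structures[[1]]$method,
    XRD = "EXPDTA    X-RAY DIFFRACTION",
    NMR = "EXPDTA    SOLUTION NMR",
    SYNTHETIC = "EXPDTA    SYNTHETIC",
    "EXPDTA    THEORETICAL MODEL")
  out <- c(sprintf("HEADER    %-40s", structures[[1]]$structure_id),
           method_line)
  multi <- length(structures) > 1L
  serial <- 0L
  for (s in structures) {
    if (multi) out <- c(out, sprintf("MODEL     %4d", s$model_number))
    res3 <- AA1TO3[s$aa]
    res3[is.na(res3)] <- "UNK"
    for (i in seq_along(s$resno)) {
      serial <- serial + 1L
      out <- c(out, sprintf(
        "ATOM  %5d  CA  %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
        serial %% 100000L, res3[i], s$chain_id, s$resno[i],
        ifelse(nzchar(s$ins[i]), s$ins[i], " "),
        s$xyz[i, 1], s$xyz[i, 2], s$xyz[i, 3], 1, 0))
    }
    if (multi) out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}

#' Residue correspondence between two same-sequence structures
#'
#' Residues are matched by residue number (plus insertion code); the
#' result lists paired indices into the model and the reference, ordered
#' by reference position.
#'
#' @param model,reference `CalphaStructure` objects sharing a numbering
#'   scheme.
#' @return list with `pairs` (2-column integer matrix: model index,
#'   reference index) and `n_reference`.
#' @export
build_correspondence <- function(model, reference) {
  km <- residue_keys(model)
  kr <- residue_keys(reference)
  ir <- which(kr %in% km)
  if (!length(ir))
    stop("disjoint numbering: no shared residue numbers between ",
         model$structure_id, " and ", reference$structure_id)
  im <- match(kr[ir], km)
  list(pairs = cbind(model = im, reference = ir),
       n_reference = length(kr))
}

aligned_coords <- function(model, reference, corr) {
  list(model = model$xyz[corr$pairs[, 1], , drop = FALSE],
       reference = reference$xyz[corr$pairs[, 2], , drop = FALSE])
}

#' Coverage of a reference by a model
#'
#' Coverage is the matched fraction of reference residues;
#' `max_consecutive_missing` is the longest run of reference positions
#' (in reference order) absent from the model. Both feed the decoy
#' filtering rule: decoys with coverage < 0.8 or a missing run longer
#' than 5 are discarded.
#'
#' @inheritParams build_correspondence
#' @return list with `coverage` and `max_consecutive_missing`.
#' @export
coverage <- function(model, reference) {
  corr <- build_correspondence(model, reference)
  present <- logical(corr$n_reference)
  present[corr$pairs[, 2]] <- TRUE
  runs <- rle(!present)
  max_run <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  list(coverage = nrow(corr$pairs) / corr$n_reference,
       max_consecutive_missing = as.integer(max_run))
}
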