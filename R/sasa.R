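# Coarse-grained solvent accessibility. Full-atom ASA cannot be computed
# from a Calpha trace, so each residue is modelled as a single sphere at
# its Calpha with a residue-specific radius derived from mean residue
# volumes; accessibility uses the Shrake-Rupley rolling-probe point
# sampling. rASA normalizes by the same sphere model evaluated in an
# extended Gly-X-Gly tripeptide, which keeps the proxy self-consistent.

# Mean amino-acid residue volumes (A^3, Zamyatnin-type consensus values),
# converted to an equivalent sphere radius r = (3V / 4 pi)^(1/3).
RESIDUE_VOLUME <- c(
  A = 88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5, Q = 143.8,
  E = 138.4, G = 60.1, H = 153.2, I = 166.7, L = 166.7, K = 168.6,
  M = 162.9, F = 189.9, P = 112.7, S = 89.0, T = 116.1, W = 227.8,
  Y = 193.6, V = 140.0, X = 140.0
)
residue_radius <- function(aa) {
  v <- RESIDUE_VOLUME[aa]
  if (any(is.na(v)))
    stop("unknown amino-acid code: ",
         paste(unique(aa[is.na(v)]), collapse = ", "))
  unname((3 * v / (4 * pi))^(1 / 3))
}

# Deterministic, nearly uniform unit-sphere points (golden-spiral lattice).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

sasa_env <- new.env(parent = emptyenv())

shrake_rupley_spheres <- function(centers, radii, probe = 1.4,
                                  n_points = 256) {
  n <- nrow(centers)
  pts <- sphere_points(n_points)
  er <- radii + probe
  asa <- numeric(n)
  for (i in seq_len(n)) {
    surf <- sweep(pts * er[i], 2, centers[i, ], "+")
    accessible <- rep(TRUE, n_points)
    for (j in seq_len(n)) {
      if (j == i) next
      dij <- sqrt(sum((centers[i, ] - centers[j, ])^2))
      if (dij >= er[i] + er[j]) next
      d2 <- rowSums(sweep(surf, 2, centers[j, ])^2)
      accessible <- accessible & d2 > er[j]^2
    }
    asa[i] <- 4 * pi * er[i]^2 * mean(accessible)
  }
  asa
}

#' Maximum per-residue ASA normalization table
#'
#' The table of maximum accessible surface areas used to normalize rASA,
#' computed with the same single-sphere residue model in an extended
#' Gly-X-Gly tripeptide (neighbours at 3.8 Angstrom on a line). The table
#' is configurable: pass any named vector of reference areas to
#' [shrake_rupley_asa()] to use a different normalization.
#'
#' @param probe probe radius (Angstrom).
#' @param n_points Shrake-Rupley sample points per sphere.
#' @return named numeric vector of maximum ASA (A^2) per one-letter code.
#' @export
max_asa_table <- function(probe = 1.4, n_points = 256) {
  key <- sprintf("gxg_%g_%d", probe, n_points)
  if (!is.null(sasa_env[[key]])) return(sasa_env[[key]])
  aas <- names(RESIDUE_VOLUME)
  rg <- residue_radius("G")
  tab <- vapply(aas, function(a) {
    centers <- rbind(c(-3.8, 0, 0), c(0, 0, 0), c(3.8, 0, 0))
    radii <- c(rg, residue_radius(a), rg)
    shrake_rupley_spheres(centers, radii, probe, n_points)[2]
  }, numeric(1))
  sasa_env[[key]] <- tab
  tab
}

#' Coarse per-residue accessible surface area
#'
#' Shrake-Rupley rolling-probe ASA of a Calpha trace in which every
#' residue is one sphere of residue-specific radius centred at its Calpha
#' (probe 1.4 Angstrom, 256 deterministic sample points by default).
#' `rasa = asa / max_asa[aa]`; because the normalization comes from a
#' flanked tripeptide, fully exposed residues can slightly exceed 1.
#'
#' @param structure a `CalphaStructure`.
#' @param probe probe radius (Angstrom).
#' @param n_points sample points per sphere (>= 256 recommended).
#' @param max_asa named normalization vector; default [max_asa_table()].
#' @return list with `resno`, `asa` (A^2) and `rasa`.
#' @export
shrake_rupley_asa <- function(structure, probe = 1.4, n_points = 256,
                              max_asa = NULL) {
  if (is.null(max_asa)) max_asa <- max_asa_table(probe, n_points)
  radii <- residue_radius(structure$aa)
  asa <- shrake_rupley_spheres(structure$xyz, radii, probe, n_points)
  norm <- max_asa[structure$aa]
  if (any(is.na(norm)))
    stop("normalization table lacks amino acid: ",
         paste(unique(structure$aa[is.na(norm)]), collapse = ", "))
  list(resno = structure$resno, asa = asa, rasa = unname(asa / norm))
}

#' Summed absolute rASA difference between two conformers
#'
#' `delta rASA = sum_i |rASA_A,i - rASA_B,i|` over residues shared by the
#' two conformers.
#'
#' @param a,b `CalphaStructure` conformers of the same protein.
#' @param ... passed to [shrake_rupley_asa()].
#' @return non-negative scalar.
#' @export
delta_rasa <- function(a, b, ...) {
  ra <- shrake_rupley_asa(a, ...)
  rb <- shrake_rupley_asa(b, ...)
  shared <- intersect(ra$resno, rb$resno)
  sum(abs(ra$rasa[match(shared, ra$resno)] -
          rb$rasa[match(shared, rb$resno)]))
}
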