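# Synthetic targets: a smoothed self-avoiding Calpha walk with curved
# (helix-like) segments, a hinge motion producing the second conformer,
# and Gaussian-noise decoy clouds with optional missing runs. All
# randomness flows from one seed; generation is bit-reproducible.

unit <- function(v) v / sqrt(sum(v^2))

perp_vector <- function(v) {
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit(pracma_cross(ref, v))
}
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

rotation_about_axis <- function(axis, angle_deg) {
  a <- unit(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Parameters of one synthetic target
#'
#' Bundles the generative parameters: chain length, hinge position and
#' angle (hinge-type domain motion), decoy counts per conformer,
#' coordinate noise, missing-run probability and the seed.
#'
#' @param n_residues chain length (>= 20).
#' @param hinge_position residue index strictly inside the chain;
#'   default the midpoint.
#' @param hinge_angle rotation of the second domain in degrees (>= 0).
#' @param n_decoys_a,n_decoys_b decoys drawn around conformers A and B.
#' @param noise_sigma per-coordinate Gaussian noise sd (Angstrom, > 0).
#' @param missing_run_prob probability that a decoy loses one run of 1-8
#'   consecutive residues.
#' @param seed integer seed; all generation randomness flows from it.
#' @param target_id identifier.
#' @return object of class `SyntheticTargetSpec`.
#' @export
synthetic_target_spec <- function(n_residues = 60L,
                                  hinge_position = NULL,
                                  hinge_angle = 30,
                                  n_decoys_a = 100L, n_decoys_b = 100L,
                                  noise_sigma = 0.5,
                                  missing_run_prob = 0,
                                  seed = 1L,
                                  target_id = sprintf("SYN%05d", seed)) {
  n_residues <- as.integer(n_residues)
  if (n_residues < 20L) stop("n_residues must be >= 20")
  if (is.null(hinge_position)) hinge_position <- n_residues %/% 2L
  hinge_position <- as.integer(hinge_position)
  if (hinge_position <= 1L || hinge_position >= n_residues)
    stop("hinge_position must be strictly inside (1, n_residues)")
  if (noise_sigma <= 0) stop("noise_sigma must be > 0")
  if (hinge_angle < 0) stop("hinge_angle must be >= 0")
  structure(list(n_residues = n_residues, hinge_position = hinge_position,
                 hinge_angle = hinge_angle,
                 n_decoys_a = as.integer(n_decoys_a),
                 n_decoys_b = as.integer(n_decoys_b),
                 noise_sigma = noise_sigma,
                 missing_run_prob = missing_run_prob,
                 seed = as.integer(seed), target_id = target_id),
            class = "SyntheticTargetSpec")
}

# One sequential chain-growth attempt; NULL on failure.
grow_chain <- function(n) {
  bond <- function() 3.8 + max(min(rnorm(1, 0, 0.02), 0.05), -0.05)
  xyz <- matrix(NA_real_, n, 3)
  xyz[1, ] <- c(0, 0, 0)
  dir <- unit(rnorm(3))
  xyz[2, ] <- xyz[1, ] + bond() * dir
  seg_left <- 0
  alpha <- 0.8
  bias <- c(0, 0, 0)
  for (i in 3:n) {
    if (seg_left == 0) {
      # new segment: curved (helix-like, strong fixed perpendicular bias)
      # or coil (weak bias, more noise)
      seg_left <- sample(5:12, 1)
      helixish <- runif(1) < 0.5
      alpha <- if (helixish) 0.75 else 0.60
      bias <- if (helixish) 0.55 * perp_vector(dir) else
        0.15 * unit(rnorm(3))
    }
    placed <- FALSE
    for (try in 1:60) {
      nd <- unit(alpha * dir + bias + 0.25 * rnorm(3))
      cand <- xyz[i - 1, ] + bond() * nd
      prev <- xyz[1:(i - 2), , drop = FALSE]
      d2 <- rowSums(sweep(prev, 2, cand)^2)
      if (all(d2 >= 4.0^2)) {
        xyz[i, ] <- cand
        dir <- nd
        placed <- TRUE
        break
      }
    }
    if (!placed) return(NULL)
    seg_left <- seg_left - 1
  }
  xyz
}

#' Generate a synthetic Calpha backbone
#'
#' Self-avoiding smoothed random walk with curved helix-like segments:
#' consecutive Calpha-Calpha distances 3.8 +/- 0.05 Angstrom, no two
#' non-adjacent Calpha closer than 4.0 Angstrom. Bit-reproducible given
#' the seed; the caller's RNG state is untouched.
#'
#' @param n_residues chain length (>= 20).
#' @param seed integer seed.
#' @param target_id structure identifier.
#' @return a `CalphaStructure` with `method = "SYNTHETIC"` and a random
#'   amino-acid sequence.
#' @export
generate_backbone <- function(n_residues, seed, target_id = "synthetic") {
  if (n_residues < 20) stop("n_residues must be >= 20")
  with_seed(seed, {
    xyz <- NULL
    for (attempt in 1:25) {
      xyz <- grow_chain(n_residues)
      if (!is.null(xyz)) break
    }
    if (is.null(xyz))
      stop("self-avoidance unsatisfiable after bounded retries; re-seed")
    aa <- sample(setdiff(names(AA1TO3), "X"), n_residues, replace = TRUE)
    calpha_structure(target_id, 1L, "A", seq_len(n_residues), aa, xyz,
                     method = "SYNTHETIC")
  })
}

#' Apply a hinge motion to a Calpha trace
#'
#' Residues after `hinge_position` rotate rigidly by `angle` degrees
#' about an axis through the hinge Calpha perpendicular to the local
#' chain direction (the incoming bond vector, so the axis is identical
#' on repeated application); residues up to the hinge are unchanged.
#' Angle 0 is the identity.
#'
#' @param structure a `CalphaStructure`.
#' @param hinge_position residue index strictly inside the chain.
#' @param angle degrees.
#' @return the hinged `CalphaStructure`.
#' @export
apply_hinge <- function(structure, hinge_position, angle) {
  n <- length(structure$resno)
  h <- as.integer(hinge_position)
  if (h <= 1L || h >= n) stop("hinge_position must be strictly inside")
  xyz <- structure$xyz
  dir <- unit(xyz[h, ] - xyz[h - 1, ])
  axis <- perp_vector(dir)
  R <- rotation_about_axis(axis, angle)
  pivot <- xyz[h, ]
  idx <- (h + 1L):n
  moved <- sweep(xyz[idx, , drop = FALSE], 2, pivot)
  xyz[idx, ] <- sweep(moved %*% t(R), 2, pivot, "+")
  out <- structure
  out$xyz <- xyz
  out
}

delete_run <- function(s, start, len) {
  keep <- setdiff(seq_along(s$resno), start:(start + len - 1L))
  calpha_structure(s$structure_id, s$model_number, s$chain_id,
                   s$resno[keep], s$aa[keep], s$xyz[keep, , drop = FALSE],
                   method = s$method, ins = s$ins[keep])
}

#' Sample a synthetic conformer pair and its decoy cloud
#'
#' Conformer A is a generated backbone; conformer B is A under the
#' hinge motion. Decoys are copies of A or B with i.i.d. Gaussian
#' coordinate noise (`noise_sigma` per coordinate) and, with probability
#' `missing_run_prob`, a deleted run of 1-8 consecutive residues. Every
#' decoy carries its true source conformer as a ground-truth label.
#'
#' @param spec a [synthetic_target_spec()].
#' @return list with `pair` (a `ConformerPair`, `cause = "UNKNOWN"`) and
#'   `decoys` (list of `DecoyRecord` with `true_source` labels).
#' @export
sample_decoys <- function(spec) {
  stopifnot(inherits(spec, "SyntheticTargetSpec"))
  base <- generate_backbone(spec$n_residues, spec$seed,
                            paste0(spec$target_id, "_A"))
  hinged <- apply_hinge(base, spec$hinge_position, spec$hinge_angle)
  hinged$structure_id <- paste0(spec$target_id, "_B")
  scores <- score_pair(base, hinged)
  pair <- new_conformer_pair(spec$target_id, base, hinged, scores)
  n_tot <- spec$n_decoys_a + spec$n_decoys_b
  decoys <- with_seed(spec$seed + 1L, {
    lapply(seq_len(n_tot), function(k) {
      from_a <- k <= spec$n_decoys_a
      src <- if (from_a) base else hinged
      s <- src
      s$structure_id <- sprintf("%s_d%04d", spec$target_id, k)
      s$method <- "MODEL"
      s$xyz <- s$xyz + matrix(rnorm(3 * length(s$resno), 0,
                                    spec$noise_sigma),
                              ncol = 3)
      if (runif(1) < spec$missing_run_prob) {
        len <- sample(1:8, 1)
        start <- sample(seq_len(length(s$resno) - len + 1L), 1)
        s <- delete_run(s, start, len)
      }
      decoy_record(s$structure_id, s, group_label = "synthetic",
                   true_source = if (from_a) "A" else "B")
    })
  })
  list(pair = pair, decoys = decoys, spec = spec)
}
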