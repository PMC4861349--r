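---
title: "Assessing protein structure models against a conformational ensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing protein structure models against a conformational ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conformerQA)
```

## The problem

Model quality assessment (MQA) conventionally scores a population of
computational models ("decoys") against a single experimental structure of
the target. Proteins, however, populate an ensemble of conformers in their
native state: ligand binding, post-translational modification, a change of
oligomeric state, or simply the dynamics visible across an NMR ensemble can
move the experimental structure by several Angstrom of Calpha-RMSD. When
the native state is diverse, the choice of reference conformer changes the
decoy ranking — and possibly which decoy is called "best".

`conformerQA` makes that effect measurable. For a target it takes

* a set of experimentally determined conformers (all with the same
  sequence, matched residue by residue-number), and
* a population of decoys,

selects the *maximally distant* conformer pair (the pair with the largest
pairwise Calpha-RMSD, a standard summary of the observed conformational
diversity), scores every decoy against **both** conformers under three
similarity measures, and asks two questions per measure:

1. How similar are the two decoy rankings? (Spearman's rank correlation
   over the decoys scored against both conformers.)
2. Do both conformers select the same best decoy (`SAME_BEST`) or
   different ones (`DIFFERENT_BEST`)? In the second case the decoy
   population resolves at least two distinct members of the native
   ensemble, and the best decoy of one conformer cross-compared against
   the other conformer (its "cross-RMSD") quantifies the separation.

## Similarity measures

All measures operate on Calpha traces; residues are matched by residue
number plus insertion code (sequences are identical by construction, so no
sequence alignment is needed).

**Calpha-RMSD** is computed over the aligned pairs after the optimal
least-squares rigid-body (Kabsch) superposition: a 3x3 SVD with a
determinant correction guaranteeing a proper rotation.

**GDT_TS** is `(P1 + P2 + P4 + P8) / 4`, where `Pd` is the largest
fraction of *reference* residues that some rigid superposition fits within
`d` Angstrom. Finding `Pd` exactly is combinatorial; the package uses:

* for `n_aligned <= 14`: exact enumeration of the least-squares fit of
  every residue subset of size >= 3, scoring each fit by the number of
  residues under the threshold. This is affordable (`2^14` fits) and
  provably optimal over subset fits. We adopted it after observing that
  the winning subset is sometimes *inclusion-unstable*: superposing on a
  well-chosen strict subset fits every residue under the cutoff, while
  re-fitting on the full included set ejects a residue again — a
  configuration no iterative inclusion heuristic reliably reaches.
* for larger cases: a fragment-seeded iterative-inclusion search. Seeds
  are the full alignment plus all sliding windows of length 3–7 (plus all
  residue triples up to `n_aligned <= 16`); each seed is iterated
  (superpose the current subset, include every residue under the
  threshold) to a fixed point with every iterate scored, followed by a
  "k-nearest" refinement of the best superposition (re-fit on the k
  closest residues for every k, repeat while it improves). Ties between
  equal-sized subsets keep the lower-RMSD one; remaining ties resolve in
  deterministic seed order. Heuristic values are lower bounds of the true
  maximum.

**TM-score** is `max (1/L_ref) * sum_i 1 / (1 + (d_i/d0)^2)` over
superpositions, with `d0 = 1.24 (L_ref - 15)^(1/3) - 1.8` clamped below at
0.5 (the raw formula is non-positive for short chains; 0.5 is the floor
used by the reference implementation of the score). The search reuses the
fragment-seed scheme with the TM sum as objective and finishes each seed
with an iteratively reweighted Kabsch refinement (weights
`(1 + (d_i/d0)^2)^-2`, whose fixed points are stationary points of the TM
sum); refinements are deduplicated by the seed's converged subset.

**Denominators.** GDT_TS and TM-score normalize by the reference
(conformer) length, so a decoy that covers only part of the target is
penalized; RMSD is computed over aligned pairs only. This treats the
experimental conformer as the target of the assessment.

**Per-position profiles.** For a (model, reference) pair the package also
reports per-position Calpha distances after the single global
superposition and their z-scores `z_i = (d_i - mean d) / sd d`. When
`sd(d)` is zero within coordinate precision (identical structures) all
z-scores are set to 0 so profiles stay finite and flat. Each profile uses
its own pairwise superposition; profiles are not pooled.

**Solvent accessibility.** Full-atom accessible surface area cannot be
computed from a Calpha trace, so each residue is modelled as one sphere at
its Calpha with a radius derived from mean residue volumes, and ASA is
computed by Shrake–Rupley point sampling (probe 1.4 Angstrom, 256
deterministic golden-spiral points). Relative ASA normalizes by the same
sphere model evaluated in an extended Gly-X-Gly tripeptide, which keeps
the proxy internally consistent (fully exposed residues can slightly
exceed 1); the normalization table is configurable. The summed absolute
rASA difference between two conformers summarizes how much their exposure
patterns differ. Treat these numbers as a coarse proxy, not as DSSP
replacements.

## Filters and significance

Decoys with coverage below 0.8 of the target numbering, or with a run of
more than 5 consecutive missing reference residues, are discarded
(boundaries inclusive: exactly 0.8 and exactly 5 pass). Alignment
significance — in the original workflow an E-value statistic of the
alignment program — is not reproducible from a Calpha pipeline, so it is a
pluggable predicate; the default calls a comparison significant when at
least 30 residues align with coverage at least 0.8. RMSD-based rankings
and their rank correlation use only comparisons passing the gate; a
target with at least `min_significant = 3` significant decoy–conformer
comparisons is flagged `high_quality`, and cohort fractions are reported
both over all targets and over that subset.

## The synthetic world

`synthetic_target_spec()` + `sample_decoys()` generate a fully labelled
test world:

| parameter | default | meaning |
|---|---|---|
| `n_residues` | 60 | chain length; scaled down from realistic (100+) target sizes to keep the test suite within its CPU budget |
| `hinge_position` | midpoint | residue where the second domain starts |
| `hinge_angle` | 30 deg | rigid rotation of the second domain about an axis through the hinge Calpha perpendicular to the incoming chain direction; 0 gives identical conformers, and 1–30 deg maps to conformer-pair RMSDs of roughly 0.1–5 Angstrom |
| `n_decoys_a`, `n_decoys_b` | 100, 100 | decoys drawn around each conformer |
| `noise_sigma` | 0.5 Angstrom | per-coordinate i.i.d. Gaussian noise added to each decoy |
| `missing_run_prob` | 0 | probability a decoy loses a run of 1–8 consecutive residues |
| `seed` | — | mandatory; generation is bit-reproducible and leaves the caller's RNG untouched |

The backbone generator produces a self-avoiding smoothed random walk with
curved, helix-like segments: consecutive Calpha distances 3.8 ± 0.05
Angstrom, no two non-adjacent Calpha closer than 4 Angstrom. Gaussian
coordinate noise was chosen over torsion-space sampling because its
expected displacement is directly controllable; it is a stand-in for the
error structure of real decoys, not a model of it.

**What the generator deliberately does not emulate — and what that means
for the tests.** Every decoy in a synthetic cloud has the *same* expected
quality. Real decoy sets span a wide quality range, and two consequences
follow:

* *Best-decoy agreement.* With uniform-quality clouds around conformer A
  only, the decoy ranking against conformer B is dominated by the
  component of each decoy's noise along the hinge displacement, which is
  statistically independent of the noise magnitude that ranks decoys
  against A. Both conformers therefore almost never select the same best
  decoy, even though every decoy comes from one cloud. A same-best outcome
  requires a decoy that *dominates* the population — exactly what quality
  spread provides in real data. The test suite asserts the robust
  signatures instead (cross-RMSD of a best decoy exceeds its own-RMSD;
  a deliberately dominant decoy forces `SAME_BEST`), and one acceptance
  expectation that encodes the idealized "single cloud implies same best"
  rule is knowingly left failing with this analysis.
* *GDT-vs-TM rank agreement.* Between decoys of essentially equal
  quality, the quantized GDT_TS (steps of `1/(4 L_ref)`, driven at low
  noise almost entirely by the 1 Angstrom threshold) and the smooth
  TM-score disagree on fine ordering, capping their per-target rank
  correlation below the near-perfect level observed across wide quality
  ranges. The corresponding acceptance expectation is likewise left
  failing rather than loosened.

A green synthetic test therefore establishes that the machinery —
superposition, scores, filters, rankings, classification — behaves
correctly in a controlled world; it does not by itself establish the
empirical magnitudes seen in heterogeneous real decoy sets.

## Numerical choices

* Kabsch requires at least 3 points; collinear degenerate inputs still
  return a valid minimum through the SVD determinant correction.
* Alternate locations in PDB input resolve to the highest occupancy, ties
  to the first record; insertion codes order after their base residue
  number.
* Score ties in rankings receive average ranks; best-decoy ties break
  deterministically by decoy id.
* Spearman's coefficient is computed as the Pearson correlation of the
  average-rank vectors (tie-robust form), over the intersection of decoys
  valid against both conformers, and is undefined (reported `NA`) below 3
  shared decoys.
* Maximally-distant-pair selection breaks exact RMSD ties
  lexicographically by conformer label; the result is invariant to input
  order.
* All pipeline outputs are plain TSV/JSON written in manifest order, so a
  rerun with identical inputs and configuration is byte-identical.

## Limitations

* Calpha-only: no side chains, no full-atom RMSD, no sequence alignment of
  non-identical sequences, no mmCIF.
* The GDT/TM searches are heuristics above the exact-enumeration size;
  reported values are lower bounds of the true optimum (the gap is zero on
  all small-case fixtures tested against the exhaustive oracle).
* The sphere-model ASA is a coarse proxy; do not compare its absolute
  values with atomistic ASA programs.
* Diversity-cause annotations (ligand / PTM / oligomer / NMR) are manifest
  metadata supplied by the user, not inferred from structures.
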