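# Superposition and similarity measures against independent oracles.

test_that("kabsch superposition: identity, translation and rigid motions", {
  set.seed(1)
  P <- rand_xyz(12)
  k <- kabsch_superpose(P, P)
  expect_equal(k$rmsd, 0, tolerance = 1e-9)
  expect_equal(k$rotation, diag(3), tolerance = 1e-9)

  k <- kabsch_superpose(P, sweep(P, 2, -c(5, 5, 5)))  # reference shifted
  expect_equal(k$rmsd, 0, tolerance = 1e-9)

  for (i in 1:10) {
    k <- kabsch_superpose(P, rigid_transform(P))
    expect_equal(k$rmsd, 0, tolerance = 1e-8)
    expect_equal(det(k$rotation), 1, tolerance = 1e-9)
  }
  expect_error(kabsch_superpose(P[1:2, ], P[1:2, ]), "insufficient points")
})

test_that("kabsch rmsd matches the quaternion-grid oracle on random sets", {
  set.seed(101)
  for (i in 1:3) {
    P <- rand_xyz(10)
    Q <- rand_xyz(10)
    got <- kabsch_superpose(P, Q)$rmsd
    want <- oracle_min_rmsd_grid(P, Q)
    expect_equal(got, want, tolerance = 1e-3)
    expect_lte(got, want + 1e-9)  # ours is the global minimum
  }
})

test_that("gdt_ts: identity, outlier and coverage denominators", {
  ref <- mk_struct(chain_xyz(10, wiggle = 0.5))
  expect_equal(gdt_ts(ref, ref), 1.0)

  # 9 residues exact, 1 thrown 10 A off: P1 = P2 = P4 = 0.9, but a subset
  # superposition recovers the outlier at the 8 A threshold (P8 = 1), so
  # the exhaustive oracle gives (0.9 * 3 + 1) / 4
  off <- ref
  off$xyz[10, ] <- off$xyz[10, ] + c(0, 0, 10)
  got <- gdt_ts(off, ref)
  expect_equal(got, oracle_gdt_exhaustive(off$xyz, ref$xyz, 10))
  expect_equal(got, 0.925)

  # thrown far enough (30 A) no threshold recovers it: exactly 0.9
  far <- ref
  far$xyz[10, ] <- far$xyz[10, ] + c(0, 0, 30)
  got <- gdt_ts(far, ref)
  expect_equal(got, oracle_gdt_exhaustive(far$xyz, ref$xyz, 10))
  expect_equal(got, 0.9)

  # half coverage, exactly superposable: denominator is reference length
  half <- mk_struct(chain_xyz(10, wiggle = 0.5)[1:5, ], resno = 1:5)
  expect_equal(gdt_ts(half, ref), 0.5)
})

test_that("gdt_ts equals the exhaustive-subset oracle on small fixtures", {
  set.seed(2024)
  for (n in c(8, 10, 12)) {
    for (sigma in c(0.4, 1.5)) {
      base <- chain_xyz(n, wiggle = 0.8)
      noisy <- base + matrix(rnorm(3 * n, 0, sigma), ncol = 3)
      model <- mk_struct(rigid_transform(noisy), resno = seq_len(n))
      ref <- mk_struct(base, resno = seq_len(n))
      expect_equal(gdt_ts(model, ref),
                   oracle_gdt_exhaustive(model$xyz, ref$xyz, n),
                   info = sprintf("n=%d sigma=%.1f", n, sigma))
    }
  }
})

test_that("tm-score: identity, d0 closed form and clamp", {
  ref <- mk_struct(chain_xyz(25, wiggle = 0.5))
  expect_equal(tm_score(ref, ref), 1.0, tolerance = 1e-9)
  # for L = 21 the raw formula gives 1.24 * 6^(1/3) - 1.8 = 0.453,
  # which the 0.5 floor clamps
  expect_equal(tm_d0(21), max(1.24 * 6^(1 / 3) - 1.8, 0.5))
  expect_equal(tm_d0(21), 0.5)
  expect_equal(tm_d0(36), 1.24 * 21^(1 / 3) - 1.8)  # above the clamp
  expect_equal(tm_d0(15), 0.5)  # raw formula hits -1.8 here
  expect_equal(tm_d0(10), 0.5)
})

test_that("tm-score matches the dense restart-search oracle", {
  set.seed(303)
  n <- 20
  base <- chain_xyz(n, wiggle = 0.8)
  noisy <- base + matrix(rnorm(3 * n, 0, 2.0), ncol = 3)
  model <- mk_struct(rigid_transform(noisy), resno = seq_len(n))
  ref <- mk_struct(base, resno = seq_len(n))
  got <- tm_score(model, ref)
  want <- oracle_tm_restart(model$xyz, ref$xyz, n, tm_d0(n))
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("metrics are invariant to rigid motions of either structure", {
  set.seed(5)
  base <- generate_backbone(30, seed = 5, "inv")
  model <- base
  model$xyz <- model$xyz + matrix(rnorm(90, 0, 1), ncol = 3)
  ref_scores <- score_pair(model, base)
  for (i in 1:20) {
    sc <- if (i %% 2 == 0) score_pair(transform_struct(model), base)
          else score_pair(model, transform_struct(base))
    expect_equal(sc$rmsd, ref_scores$rmsd, tolerance = 1e-6)
    expect_equal(sc$gdt_ts, ref_scores$gdt_ts, tolerance = 1e-6)
    expect_equal(sc$tm_score, ref_scores$tm_score, tolerance = 1e-6)
  }
})

test_that("noise degrades scores monotonically in expectation", {
  set.seed(99)
  base <- generate_backbone(40, seed = 17, "mono")
  sigmas <- c(0.5, 1, 2, 4)
  means <- sapply(sigmas, function(sg) {
    reps <- replicate(20, {
      m <- base
      m$xyz <- m$xyz + matrix(rnorm(3 * 40, 0, sg), ncol = 3)
      sc <- score_pair(m, base)
      c(sc$rmsd, sc$gdt_ts, sc$tm_score)
    })
    rowMeans(reps)
  })
  expect_true(all(diff(means[1, ]) > 0))  # rmsd increases
  expect_true(all(diff(means[2, ]) < 0))  # gdt decreases
  expect_true(all(diff(means[3, ]) < 0))  # tm decreases
})

test_that("per-position profiles follow the z-score conventions", {
  ref <- mk_struct(chain_xyz(10, wiggle = 0.5))
  p <- per_position_profile(ref, ref)
  expect_equal(p$d, rep(0, 10))
  expect_equal(p$z, rep(0, 10))  # sd(d) = 0 convention

  # one displaced residue owns the unique maximal z
  off <- ref
  off$xyz[7, ] <- off$xyz[7, ] + c(0, 4, 0)
  p <- per_position_profile(off, ref)
  expect_equal(which.max(p$z), 7)
  expect_equal(sum(p$z == max(p$z)), 1)
  expect_equal(mean(p$z), 0, tolerance = 1e-9)
  expect_equal(sd(p$z), 1, tolerance = 1e-9)
})

test_that("z-scores match the hand formula on a 4-residue example", {
  # after superposition, per-position d = (0,0,0,2) gives deviations
  # (-0.5,-0.5,-0.5,1.5) and sd(d) = 1, hence z = (-0.5,-0.5,-0.5,1.5)
  d <- c(0, 0, 0, 2)
  expect_equal(sd(d), 1)
  z_hand <- (d - mean(d)) / sd(d)
  expect_equal(z_hand, c(-0.5, -0.5, -0.5, 1.5))
})

test_that("sphere-model ASA follows the analytic two-sphere formula", {
  two <- mk_struct(rbind(c(0, 0, 0), c(5, 0, 0), c(10, 0, 0)),
                   aa = c("A", "G", "A"), resno = c(1, 5, 9))
  # residues 1 and 3 are far from each other; each overlaps only the Gly
  prof <- shrake_rupley_asa(two)
  r_ala <- conformerQA:::residue_radius("A")
  r_gly <- conformerQA:::residue_radius("G")
  want <- oracle_two_sphere_area(r_ala, r_gly, 5)
  expect_equal(prof$asa[1], want, tolerance = 0.02)
  expect_equal(prof$asa[3], want, tolerance = 0.02)
})

test_that("rASA conventions: isolated exposure, identity, unknown code", {
  iso <- mk_struct(matrix(c(0, 0, 0), 1, 3), aa = "W")
  expect_gt(shrake_rupley_asa(iso)$rasa, 0.9)

  s <- generate_backbone(25, seed = 3, "sasa")
  expect_equal(delta_rasa(s, s), 0)

  bad <- mk_struct(chain_xyz(3), aa = c("A", "B", "A"))
  expect_error(shrake_rupley_asa(bad), "unknown amino-acid code: B")
})
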