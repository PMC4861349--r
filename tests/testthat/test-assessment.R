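# Decoy filtering, ranking, rank correlation and target assessment.

test_that("decoy filters: coverage and missing-run boundaries", {
  ref <- generate_backbone(100, seed = 31, "filt")
  decoys <- list(
    derive_decoy(ref, "cov79", drop = 1:21),          # coverage 0.79
    derive_decoy(ref, "run6", drop = 40:45),          # run of 6, cov 0.94
    derive_decoy(ref, "edge",                         # cov 0.80, max run 5
                 drop = c(1:5, 20:24, 40:44, 60:64)),
    derive_decoy(ref, "full")
  )
  out <- filter_decoys(decoys, ref)
  passed <- vapply(out, `[[`, logical(1), "passed_filters")
  expect_equal(setNames(passed, c("cov79", "run6", "edge", "full")),
               c(cov79 = FALSE, run6 = FALSE, edge = TRUE, full = TRUE))

  # unbuildable correspondence fails the filters instead of erroring
  alien <- derive_decoy(ref, "alien")
  alien$structure$resno <- alien$structure$resno + 1000L
  out <- filter_decoys(list(alien), ref)
  expect_false(out[[1]]$passed_filters)
})

test_that("significance gate stores the predicate verdict", {
  ref <- generate_backbone(100, seed = 32, "sig")
  sc <- score_pair(ref, ref)
  expect_true(sc$significant)

  short <- derive_decoy(ref, "short", drop = 11:100)$structure
  sc <- score_pair(short, ref)   # 10 of 100 residues
  expect_false(sc$significant)
  expect_equal(sc$coverage, 0.1)

  # full-coverage noisy decoy is significant under the default predicate
  noisy <- derive_decoy(ref, "noisy", sigma = 1)$structure
  expect_true(score_pair(noisy, ref)$significant)

  # the predicate is pluggable
  sc <- score_pair(noisy, ref, predicate = function(s) s$rmsd < 0.1)
  expect_false(sc$significant)
})

test_that("rank_decoys directions and average-rank ties", {
  r <- rank_decoys(c(d1 = 1.0, d2 = 2.0, d3 = 0.5), "RMSD")
  expect_equal(r$decoy_id, c("d3", "d1", "d2"))
  expect_equal(r$rank, c(1, 2, 3))

  r <- rank_decoys(c(x = 0.8, y = 0.8, z = 0.5), "GDT_TS")
  expect_equal(r$rank[r$decoy_id %in% c("x", "y")], c(1.5, 1.5))
  expect_equal(r$rank[r$decoy_id == "z"], 3)

  set.seed(44)
  scores <- setNames(round(runif(100), 2), sprintf("d%03d", 1:100))
  r <- rank_decoys(scores, "TM")
  want <- oracle_rank(scores, decreasing = TRUE)
  expect_equal(r$rank, unname(want$ranks[r$decoy_id]))
  expect_error(rank_decoys(numeric(0), "RMSD"), "no scored decoys")
})

test_that("spearman_rho: extremes and the tie-corrected hand value", {
  ra <- rank_decoys(setNames(1:6 / 10, letters[1:6]), "RMSD")
  expect_equal(spearman_rho(ra, ra), 1.0)
  rb <- rank_decoys(setNames(6:1 / 10, letters[1:6]), "RMSD")
  expect_equal(spearman_rho(ra, rb), -1.0)

  # ranks (1, 2.5, 2.5, 4) vs (1, 2, 3, 4): product-moment correlation of
  # the average-rank vectors = 4.5 / sqrt(4.5 * 5) = 0.9486833
  ta <- rank_decoys(c(w = 1, x = 2, y = 2, z = 3), "RMSD")
  tb <- rank_decoys(c(w = 1, x = 2, y = 3, z = 4), "RMSD")
  expect_equal(spearman_rho(ta, tb), 0.9486833, tolerance = 1e-7)

  # fewer than 3 shared decoys is undefined
  expect_true(is.na(spearman_rho(ta[1:2, ], tb)))
})

test_that("assess_target recovers designed cloud structure", {
  # single cloud around A: the decoy best against A sits near A, so its
  # cross-RMSD against B is dominated by the conformer separation. (Note
  # uniform-noise clouds do NOT force both conformers onto the same best
  # decoy identity: the ranking against B is driven by the noise
  # component along the hinge displacement, nearly independent of the
  # ranking against A. See the methods vignette.)
  for (seed in c(501, 502, 503)) {
    spec <- synthetic_target_spec(seed = seed, hinge_angle = 30,
                                  noise_sigma = 0.5,
                                  n_decoys_a = 20L, n_decoys_b = 0L)
    g <- sample_decoys(spec)
    a <- assess_target(g$pair, g$decoys, metrics = "RMSD")
    rows <- a$best[a$best$metric == "RMSD", ]
    own_a <- rows$rmsd_own[rows$conformer == "a"]
    expect_lt(own_a, 3 * spec$noise_sigma)
    expect_gt(rows$rmsd_cross[rows$conformer == "a"], own_a)
    expect_gt(mean(rows$rmsd_cross), mean(rows$rmsd_own))
  }

  # one decoy strictly dominating the population is best for BOTH
  # conformers: the designed SAME_BEST case
  spec <- synthetic_target_spec(seed = 504, hinge_angle = 30,
                                n_decoys_a = 1L, n_decoys_b = 0L)
  g <- sample_decoys(spec)
  set.seed(504)
  decoys <- c(list(derive_decoy(g$pair$conformer_a, "dom", sigma = 0.05)),
              lapply(1:10, function(i)
                derive_decoy(g$pair$conformer_a, sprintf("bad%02d", i),
                             sigma = 3)))
  a <- assess_target(g$pair, decoys, metrics = "RMSD")
  expect_equal(unname(a$classification["RMSD"]), "SAME_BEST")
  expect_equal(a$best$decoy_id, c("dom", "dom"))

  for (seed in c(601, 602, 603)) {
    spec <- synthetic_target_spec(seed = seed, hinge_angle = 30,
                                  noise_sigma = 0.5,
                                  n_decoys_a = 15L, n_decoys_b = 15L)
    g <- sample_decoys(spec)
    a <- assess_target(g$pair, g$decoys, metrics = "RMSD")
    expect_equal(unname(a$classification["RMSD"]), "DIFFERENT_BEST")
  }
})

test_that("identical conformers give rho 1 for all metrics", {
  spec <- synthetic_target_spec(seed = 71, hinge_angle = 0,
                                n_decoys_a = 8L, n_decoys_b = 8L)
  g <- sample_decoys(spec)
  a <- assess_target(g$pair, g$decoys)
  expect_equal(unname(a$spearman_rho), rep(1, 3), tolerance = 1e-12)
  expect_equal(unname(a$classification), rep("SAME_BEST", 3))
})

test_that("zero passed decoys yields a flagged assessment", {
  spec <- synthetic_target_spec(seed = 81, n_decoys_a = 3L,
                                n_decoys_b = 3L)
  g <- sample_decoys(spec)
  ref <- g$pair$conformer_a
  bad <- lapply(g$decoys, function(d) {
    d$structure <- derive_decoy(ref, d$decoy_id, drop = 1:20)$structure
    d
  })
  a <- assess_target(g$pair, bad)
  expect_true(a$flagged)
  expect_equal(a$n_decoys_passed, 0)
  expect_true(all(is.na(a$spearman_rho)))
})

test_that("cohort_report fractions and complements", {
  # 3 balanced two-cloud targets (DIFFERENT_BEST) + 2 dominant-decoy
  # targets (SAME_BEST by construction)
  as_ <- lapply(c(901, 902, 903), function(s) {
    g <- sample_decoys(synthetic_target_spec(seed = s, n_decoys_a = 12L,
                                             n_decoys_b = 12L))
    assess_target(g$pair, g$decoys, metrics = "RMSD")
  })
  for (s in c(904, 905)) {
    g <- sample_decoys(synthetic_target_spec(seed = s, n_decoys_a = 1L,
                                             n_decoys_b = 0L))
    set.seed(s)
    decoys <- c(list(derive_decoy(g$pair$conformer_a, "dom", sigma = 0.05)),
                lapply(1:8, function(i)
                  derive_decoy(g$pair$conformer_a, sprintf("bad%02d", i),
                               sigma = 3)))
    as_ <- c(as_, list(assess_target(g$pair, decoys, metrics = "RMSD")))
  }
  rep <- cohort_report(as_)
  row <- rep$per_metric[rep$per_metric$metric == "RMSD", ]
  expect_equal(row$frac_same_best + row$frac_different_best, 1)
  expect_equal(row$n_classified, 5)
  # the 2 single-cloud targets are SAME_BEST by design
  expect_equal(row$frac_same_best, 2 / 5)
  expect_gt(row$mean_best_rmsd_cross_diff, row$mean_best_rmsd_own_diff)
  expect_equal(rep$n_targets, 5)
})
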