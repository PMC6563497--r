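test_that("correlated noise reproduces the requested correlation structure", {
  set.seed(42)
  n <- 1e5
  # independence: identity correlation leaves all pairs uncorrelated
  e <- sample_correlated_noise(n, diag(3), sds = c(1, 2, 3))
  r <- cor(e)
  expect_true(all(abs(r[upper.tri(r)]) < 0.02))
  expect_equal(unname(apply(e, 2, sd)), c(1, 2, 3), tolerance = 0.02)

  # degenerate limit: perfect correlation gives identical standardised columns
  r2 <- matrix(c(1, 1 - 1e-12, 1 - 1e-12, 1), 2, 2)
  e2 <- sample_correlated_noise(1000, r2, sds = c(1, 1))
  expect_equal(e2[, 1], e2[, 2], tolerance = 1e-4)

  # the study's between-metric matrix is recovered within Monte-Carlo error
  R <- default_noise_correlation()
  e3 <- sample_correlated_noise(n, R, sds = rep(1, 4))
  expect_true(max(abs(cor(e3) - R)) < 0.01)
})

test_that("noise sampling rejects bad inputs", {
  bad <- matrix(c(1, 2, 2, 1), 2, 2)  # not positive definite
  expect_error(sample_correlated_noise(10, bad, c(1, 1)), "positive definite")
  expect_error(sample_correlated_noise(10, diag(2), c(1, 1, 1)), "length")
  expect_error(cohort_spec(noise_correlation = {
    R <- default_noise_correlation(); R["FA", "RD"] <- R["RD", "FA"] <- -1.9; R
  }), "positive definite")
})

test_that("effect table sign conventions are enforced", {
  et <- default_effect_table(); et["FA", "T2L"] <- 0.5
  expect_error(cohort_spec(effect_table = et), "FA/MTR/MWF")
  et <- default_effect_table(); et["RD", "NAWM"] <- -0.1
  expect_error(cohort_spec(effect_table = et), "RD")
})

test_that("lesion placement respects the T1L core fraction and disjointness", {
  spec0 <- tiny_spec(t1l_core_fraction = 0)
  set.seed(7)
  lab <- place_lesions(spec0)
  expect_true(sum(lab == 2L) > 0)
  expect_identical(sum(lab == 3L), 0L)

  spec1 <- tiny_spec(t1l_core_fraction = 1)
  set.seed(7)
  lab1 <- place_lesions(spec1)
  expect_identical(sum(lab1 == 2L), 0L)
  expect_true(sum(lab1 == 3L) > 0)

  # labels are exclusive by construction: a voxel is exactly one of 0/1/2/3
  co <- generate_cohort(tiny_spec(seed = 11))
  for (p in cohort_patients(co))
    expect_true(all(p$true_labels %in% 0:3))
})

test_that("cohorts are bit-identical under the same spec and differ across seeds", {
  a <- generate_cohort(tiny_spec(seed = 5))
  b <- generate_cohort(tiny_spec(seed = 5))
  c <- generate_cohort(tiny_spec(seed = 6))
  expect_identical(a$subjects[[1]]$maps, b$subjects[[1]]$maps)
  expect_identical(a$subjects[[12]]$true_labels, b$subjects[[12]]$true_labels)
  expect_false(identical(a$subjects[[1]]$maps$FA, c$subjects[[1]]$maps$FA))
})

test_that("generated T1w intensities respect the classification cutoff", {
  co <- generate_cohort(tiny_spec(seed = 9))
  cutoff <- co$t1_cutoff_truth
  for (p in cohort_patients(co)) {
    expect_true(all(p$t1w[p$true_labels == 3L] < cutoff))
    expect_true(all(p$t1w[p$true_labels == 2L] > cutoff))
  }
})

test_that("a null configuration produces patients indistinguishable from controls", {
  spec <- tiny_spec(seed = 21,
                    effect_table = default_effect_table() * 0,
                    between_patient_effect_sd = default_effect_sd() * 0)
  co <- generate_cohort(spec)
  models <- lapply(spec$metrics, function(m)
    fit_normative(lapply(cohort_controls(co), function(s) s$maps[[m]]), m))
  names(models) <- spec$metrics
  wm <- co$wm_probability >= 0.8
  meds <- sapply(cohort_patients(co), function(p)
    global_damage(zscore_map(p$maps$FA, models$FA), wm))
  expect_lt(abs(mean(meds)), 0.15)  # |mean z| near 0 under the null
})

test_that("rater simulation spans the degenerate limits and is asymmetric", {
  co <- generate_cohort(tiny_spec(seed = 3))
  mask <- cohort_patients(co)[[1]]$true_labels >= 2L
  set.seed(1)
  r0 <- simulate_raters(mask, erosion_prob = c(0, 0))
  expect_equal(dice(r0[[1]], r0[[2]]), 1)
  expect_identical(r0[[1]], mask)
  set.seed(1)
  r1 <- simulate_raters(mask, erosion_prob = c(0, 1))
  expect_equal(dice(r1[[1]], r1[[2]]), 0)  # full erosion of one rater
  expect_identical(sum(r1[[2]]), 0L)
  # the higher-probability rater marks systematically less tissue
  set.seed(2)
  vols <- replicate(20, {
    r <- simulate_raters(mask, erosion_prob = c(0.2, 0.5))
    c(sum(r[[1]]), sum(r[[2]]))
  })
  expect_gt(mean(vols[1, ] - vols[2, ]), 0)
  expect_error(simulate_raters(array(FALSE, dim(mask))), "nonempty")
})

test_that("rater perturbation matches its closed-form expected Dice", {
  # with independent voxel drops at probability p^depth, E|A n B| and E|A|
  # follow directly from the per-depth keep probabilities; the ratio of
  # expectations approximates E[Dice] well for masks of this size
  co <- generate_cohort(tiny_spec(seed = 13))
  probs <- c(0.35, 0.55)
  set.seed(99)
  sims <- sapply(cohort_patients(co), function(p) {
    mask <- p$true_labels >= 2L
    r <- simulate_raters(mask, probs)
    dice(r[[1]], r[[2]])
  })
  expected <- sapply(cohort_patients(co), function(p) {
    mask <- p$true_labels >= 2L
    d <- wmdamage:::erosion_depth(mask)[mask]
    k1 <- 1 - probs[1]^d; k2 <- 1 - probs[2]^d
    2 * sum(k1 * k2) / (sum(k1) + sum(k2))
  })
  expect_equal(mean(sims), mean(expected), tolerance = 0.05)
})
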