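test_that("lesion probability map is the voxel-wise lesioned fraction", {
  dm <- c(4, 4, 4)
  m1 <- array(FALSE, dm); m1[1, 1, 1] <- TRUE
  expect_equal(build_lesion_probability_map(list(m1))$probabilities, m1 + 0)

  masks <- c(rep(list(m1), 6), rep(list(array(FALSE, dm)), 114))
  p <- build_lesion_probability_map(masks)
  expect_equal(p$probabilities[1, 1, 1], 0.05)  # 6 of 120 patients

  singles <- lapply(1:4, function(i) { m <- array(FALSE, dm); m[i, 2, 2] <- TRUE; m })
  ps <- build_lesion_probability_map(singles)$probabilities
  expect_true(all(ps[ps > 0] == 1 / 4))
  expect_error(build_lesion_probability_map(list()), "at least one")
})

test_that("susceptibility threshold is inclusive at exactly 5%", {
  p <- array(c(0.05, 0.049, 0, 0.2), c(4, 1, 1))
  s <- threshold_susceptibility(list(probabilities = p), 0.05)
  expect_identical(as.vector(s), c(TRUE, FALSE, FALSE, TRUE))
  expect_false(any(threshold_susceptibility(array(0, c(2, 2, 2)))))
  expect_error(threshold_susceptibility(p, 0), "\\(0, 1\\)")
})

test_that("NAWM exclusion uses Euclidean mm distance with the stated boundary", {
  dm <- c(21, 21, 21)
  wm <- array(1, dm)
  sus <- array(TRUE, dm)
  lesion <- array(FALSE, dm); lesion[11, 11, 11] <- TRUE
  nawm <- make_nawm_mask(wm, lesion, sus, voxel_size = c(1, 1, 1))
  # centre distances: (3,4,0) -> 5 mm (excluded, "within 5 mm"); (5,1,0) -> 5.1 mm kept
  expect_false(nawm[11 + 3, 11 + 4, 11])
  expect_false(nawm[11 + 4, 11 + 2, 11])   # sqrt(20) = 4.47 mm
  expect_true(nawm[11 + 5, 11 + 2, 11])    # sqrt(29) = 5.39 mm
  # no lesions: NAWM reduces to thresholded WM within the susceptibility mask
  none <- array(FALSE, dm)
  expect_identical(make_nawm_mask(wm, none, sus, c(1, 1, 1)), sus)
})

test_that("anisotropic exclusion matches the brute-force all-pairs mm oracle", {
  set.seed(17)
  dm <- c(20, 20, 10)
  vs <- c(1, 1, 2)  # slab voxels: exclusion shell thinner in voxel units along z
  lesion <- array(FALSE, dm)
  lesion[cbind(sample(4:17, 5), sample(4:17, 5), sample(3:8, 5))] <- TRUE
  near <- wmdamage:::dilate_mm(lesion, 5, vs)
  expect_identical(near, brute_force_near(lesion, 5, vs))
  wm <- array(1, dm); sus <- array(TRUE, dm)
  expect_identical(make_nawm_mask(wm, lesion, sus, vs), !near)
})

test_that("T1 classification reproduces the hand-computed quartile cutoff", {
  dm <- c(4, 4, 1)
  t1w <- array(200, dm)
  nawm <- array(FALSE, dm); nawm[1:8] <- TRUE
  t1w[1:8] <- c(90, 100, 110, 120, 130, 140, 150, 160)
  lesion <- array(FALSE, dm); lesion[9:10] <- TRUE
  t1w[9] <- 50; t1w[10] <- 60
  cls <- classify_lesion_voxels(t1w, lesion, nawm)
  rep <- cls$cutoff_report
  expect_equal(rep$q1, 107.5)       # linear-interpolation quartiles
  expect_equal(rep$iqr, 35)
  expect_equal(rep$cutoff, 55)
  expect_true(cls$t1l[9]); expect_false(cls$t1l[10]); expect_true(cls$t2l[10])
  expect_lt(rep$cutoff, rep$q1)
  # all lesion intensities above the cutoff: T1L empty, T2L is the lesion mask
  t1w[9] <- 100
  cls2 <- classify_lesion_voxels(t1w, lesion, nawm)
  expect_identical(sum(cls2$t1l), 0L)
  expect_identical(cls2$t2l, lesion)
  expect_error(classify_lesion_voxels(t1w, lesion, array(FALSE, dm)), "empty NAWM")
})

test_that("classification is equivariant under intensity shifts", {
  set.seed(23)
  dm <- c(8, 8, 8)
  nawm <- array(runif(512) < 0.5, dm)
  lesion <- !nawm & array(runif(512) < 0.3, dm)
  t1w <- array(rnorm(512, 100, 10), dm)
  a <- classify_lesion_voxels(t1w, lesion, nawm)
  b <- classify_lesion_voxels(t1w + 37.5, lesion, nawm)
  expect_equal(b$cutoff_report$cutoff, a$cutoff_report$cutoff + 37.5)
  expect_identical(a$t1l, b$t1l)
  expect_identical(a$t2l, b$t2l)
})

test_that("inclusion rule is strict at the 0.4 cm^3 boundary", {
  expect_true(apply_inclusion_rule(c(NAWM = 62.9, T2L = 7.0, T1L = 3.3)))
  expect_false(apply_inclusion_rule(c(NAWM = 62.9, T2L = 7.0, T1L = 0.4)))
  expect_false(apply_inclusion_rule(c(NAWM = 62.9, T2L = 0, T1L = 3.3)))
  # 400 voxels of 1 mm^3 are exactly 0.4 cm^3, hence excluded
  m <- array(FALSE, c(10, 10, 10)); m[1:400] <- TRUE
  expect_equal(mask_volume_cm3(m, c(1, 1, 1)), 0.4)
  expect_false(apply_inclusion_rule(c(NAWM = 10, T2L = 1, T1L = mask_volume_cm3(m, c(1, 1, 1)))))
})

test_that("segmentation partitions the restricted lesion mask and recovers truth", {
  co <- generate_cohort(tiny_spec(seed = 2))
  pats <- cohort_patients(co)
  lesions <- lapply(pats, function(p) p$true_labels >= 2L)
  sus <- threshold_susceptibility(build_lesion_probability_map(lesions))
  acc <- sapply(seq_along(pats), function(i) {
    ts <- segment_tissue_states(co$wm_probability, lesions[[i]], sus,
                                pats[[i]]$t1w, co$spec$voxel_size,
                                min_volume_cm3 = 0.05)
    # partition invariants
    expect_identical(ts$t1l | ts$t2l, lesions[[i]] & sus)
    expect_false(any(ts$t1l & ts$t2l))
    expect_false(any(ts$nawm & (ts$t1l | ts$t2l)))
    # voxel-level agreement with generator ground truth (margin >= 1 NAWM-SD)
    truth_t1l <- pats[[i]]$true_labels == 3L & sus
    lesioned <- lesions[[i]] & sus
    mean((ts$t1l == truth_t1l)[lesioned])
  })
  expect_gt(mean(acc), 0.95)

  # raising the susceptibility threshold never grows any mask
  pm <- build_lesion_probability_map(lesions)
  s1 <- threshold_susceptibility(pm, 0.05)
  s2 <- threshold_susceptibility(pm, 0.3)
  t1 <- segment_tissue_states(co$wm_probability, lesions[[1]], s1, pats[[1]]$t1w,
                              co$spec$voxel_size, min_volume_cm3 = 0.05)
  t2 <- segment_tissue_states(co$wm_probability, lesions[[1]], s2, pats[[1]]$t1w,
                              co$spec$voxel_size, min_volume_cm3 = 0.05)
  expect_true(all(t2$t2l <= t1$t2l))
  expect_true(all(t2$t1l <= t1$t1l))
  expect_true(all(t2$nawm <= t1$nawm))
})

test_that("the more conservative of two rater masks drives segmentation", {
  co <- generate_cohort(tiny_spec(seed = 4))
  p <- cohort_patients(co)[[1]]
  sus <- array(TRUE, dim(p$t1w))
  ts <- segment_tissue_states(co$wm_probability, p$rater_masks, sus, p$t1w,
                              co$spec$voxel_size, min_volume_cm3 = 0.01)
  conservative <- p$rater_masks[[which.min(sapply(p$rater_masks, sum))]]
  expect_identical(ts$t1l | ts$t2l, conservative & sus)
})
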