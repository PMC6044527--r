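# Evaluation metrics: DSC, 95-percentile surface distance, volume
# difference, cohort summaries.

test_that("dsc handles the standard cases and is symmetric", {
  a <- sphere_mask(c(21L, 21L, 21L), 6)
  expect_equal(dsc(a, a), 1)
  empty <- region_map(array(0L, c(21, 21, 21)))
  expect_equal(dsc(empty, empty), 1)   # both-empty convention
  expect_equal(dsc(a, empty), 0)
  c1 <- array(0L, c(8, 8, 8)); c1[1:2, 1:2, 1:2] <- 1L
  c2 <- array(0L, c(8, 8, 8)); c2[1:2, 1:2, 2:3] <- 1L
  expect_equal(dsc(region_map(c1), region_map(c2)), 0.5)  # 2*4/16
  b <- sphere_mask(c(21L, 21L, 21L), 8)
  expect_identical(dsc(a, b), dsc(b, a))
})

test_that("mhd95 equals the exhaustive-loop oracle", {
  expect_equal(mhd95(sphere_mask(c(15L, 15L, 15L), 4),
                     sphere_mask(c(15L, 15L, 15L), 4)), 0)
  s1 <- array(0L, c(8, 8, 8)); s1[2, 2, 2] <- 1L
  s2 <- array(0L, c(8, 8, 8)); s2[5, 2, 2] <- 1L
  expect_equal(mhd95(region_map(s1), region_map(s2)), 3)
  set.seed(9)
  for (k in 1:4) {
    a <- random_map(c(6L, 6L, 6L), 0.4)
    b <- random_map(c(6L, 6L, 6L), 0.4)
    if (sum(a$labels) == 0L || sum(b$labels) == 0L) next
    expect_equal(mhd95(a, b), brute_mhd95(a, b), tolerance = 1e-10)
    expect_equal(mhd95(a, b), mhd95(b, a))
  }
  # anisotropic spacing is honored
  sp <- c(1, 1, 4)
  t1 <- region_map(s1, sp); t2 <- array(0L, c(8, 8, 8)); t2[2, 2, 3] <- 1L
  expect_equal(mhd95(t1, region_map(t2, sp)), 4)
  expect_error(mhd95(region_map(array(0L, c(4, 4, 4))),
                     region_map(array(c(0L, 1L), c(4, 4, 4)))), "empty")
})

test_that("pkvd is the gt-normalized volume difference", {
  gt <- region_map(array(c(rep(1L, 100), rep(0L, 412)), c(8, 8, 8)))
  seg <- region_map(array(c(rep(1L, 110), rep(0L, 402)), c(8, 8, 8)))
  expect_equal(pkvd(seg, gt), 10)
  expect_equal(pkvd(gt, gt), 0)
  # not symmetric: normalization is by the ground truth
  expect_false(isTRUE(all.equal(pkvd(seg, gt), pkvd(gt, seg))))
  # volume-only: scattering the same count changes nothing
  scat <- array(0L, c(8, 8, 8)); scat[seq(1, 512, length.out = 110)] <- 1L
  scat <- region_map(array(scat, c(8, 8, 8)))
  expect_equal(pkvd(scat, gt), 10)
  expect_error(pkvd(seg, region_map(array(0L, c(8, 8, 8)))), "empty")
})

test_that("cohort evaluation reports summaries and paired tests", {
  a <- sphere_mask(c(17L, 17L, 17L), 5)
  pairs <- list(s1 = list(seg = a, gt = a), s2 = list(seg = a, gt = a),
                s3 = list(seg = a, gt = a))
  ev <- evaluate_cohort(pairs)
  expect_equal(ev$summary$dsc[["mean"]], 1)
  expect_equal(ev$summary$dsc[["sd"]], 0)
  # identical method columns: zero-variance differences are flagged
  ev2 <- evaluate_cohort(pairs, lapply(pairs, `[[`, "seg"))
  expect_true(ev2$t_tests$dsc$zero_variance)
  expect_true(is.na(ev2$t_tests$dsc$p_value))
  # hand-computed mean +/- SD on three synthetic scores
  b5 <- sphere_mask(c(17L, 17L, 17L), 4)
  b6 <- sphere_mask(c(17L, 17L, 17L), 6)
  pairs3 <- list(list(seg = a, gt = a), list(seg = b5, gt = a),
                 list(seg = b6, gt = a))
  scores <- c(dsc(a, a), dsc(b5, a), dsc(b6, a))
  ev3 <- evaluate_cohort(pairs3)
  expect_equal(ev3$summary$dsc[["mean"]], mean(scores))
  expect_equal(ev3$summary$dsc[["sd"]], sd(scores))
  expect_equal(ev3$summary$dsc[["min"]], min(scores))
  expect_equal(ev3$summary$dsc[["max"]], max(scores))
  # a real paired test when the columns differ
  ev4 <- evaluate_cohort(pairs3, list(b5, b6, a))
  expect_false(ev4$t_tests$dsc$zero_variance)
  expect_true(ev4$t_tests$dsc$p_value > 0 && ev4$t_tests$dsc$p_value <= 1)
  expect_error(evaluate_cohort(pairs3[1]), ">= 2")
})
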