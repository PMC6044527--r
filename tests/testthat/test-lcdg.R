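# First-order LCDG appearance model.

test_that("histograms are proper and respect masks", {
  v <- volume(array(7L, c(4, 4, 4)), quantize = FALSE)
  h <- build_histogram(v)
  expect_equal(sum(h), 1)
  expect_equal(as.numeric(h[8]), 1)  # unit spike at 7
  a <- array(c(rep(10L, 256), rep(200L, 256)), c(8, 8, 8))
  h2 <- build_histogram(volume(a, quantize = FALSE))
  expect_equal(as.numeric(h2[c(11, 201)]), c(0.5, 0.5))
  m <- region_map(array(a == 10L, c(8, 8, 8)))
  hm <- build_histogram(volume(a, quantize = FALSE), m)
  expect_equal(as.numeric(hm[11]), 1)
  empty <- region_map(array(0L, c(8, 8, 8)))
  expect_error(build_histogram(volume(a, quantize = FALSE), empty), "empty")
})

test_that("discrete Gaussians are proper distributions", {
  for (mu in c(-10, 0.3, 128, 300)) {
    p <- discrete_gaussian(mu, 7)
    expect_equal(sum(p), 1)
    expect_true(all(p >= 0))
  }
})

test_that("dominant EM recovers the generating bimodal parameters", {
  # oracle: the known generating parameters of the simulation
  set.seed(1)
  n <- 1e6
  samp <- c(rnorm(n / 2, 60, 10), rnorm(n / 2, 160, 15))
  h <- hist_from_samples(samp)
  m <- fit_dominant(h)
  comp <- m$components
  expect_equal(comp$mean, c(60, 160), tolerance = 2 / 60)  # +/- 2 levels
  expect_equal(comp$weight, c(0.5, 0.5), tolerance = 0.04) # +/- 0.02 abs
  expect_identical(comp$class, c(0L, 1L))                  # kidney brighter
  mf <- fit_dominant(h, kidney_brighter = FALSE)
  expect_identical(mf$components$class, c(1L, 0L))
})

test_that("two spikes give spike means with sigma at the lower bound", {
  h <- numeric(256); h[51] <- 0.7; h[201] <- 0.3
  h <- structure(h, class = "gray_histogram", n = 1000, q_levels = 256L)
  m <- fit_dominant(h)
  expect_equal(m$components$mean, c(50, 200), tolerance = 1e-6)
  expect_equal(m$components$sd, c(0.5, 0.5))
  one <- structure(c(1, numeric(255)), class = "gray_histogram",
                   n = 10, q_levels = 256L)
  expect_error(fit_dominant(one), "degenerate")
})

test_that("subordinates only improve the fit and keep the density valid", {
  # a histogram that IS a 2-DG mixture gets (almost) no subordinate mass
  h0 <- 0.45 * discrete_gaussian(70, 12) + 0.55 * discrete_gaussian(180, 18)
  h0 <- structure(h0, class = "gray_histogram", n = 1e6, q_levels = 256L)
  m0 <- fit_lcdg(h0, tol = 1e-4)
  subw <- m0$components$weight[m0$components$role == "subordinate"]
  expect_true(all(abs(subw) < 0.01))
  # skewed histogram: subordinates strictly reduce the L1 error
  set.seed(7)
  samp <- c(rgamma(4e5, shape = 4, scale = 12),
            rnorm(6e5, 170, 20) + rexp(6e5, 0.1))
  h <- hist_from_samples(samp)
  dom <- fit_dominant(h)
  l1_dom <- sum(abs(h - kidneyseg:::lcdg_mixture(dom$components, 256)))
  full <- fit_lcdg(h)
  expect_lt(full$l1_error, l1_dom)
  dens <- kidneyseg:::lcdg_mixture(full$components, 256)
  expect_gte(min(dens), -1e-12)
  expect_equal(sum(full$components$weight), 1, tolerance = 1e-8)
  # monotone improvement in the subordinate cap
  l1s <- vapply(0:4, function(k) fit_lcdg(h, max_subordinate = k)$l1_error, 0)
  expect_true(all(diff(l1s) <= 1e-12))
})

test_that("class splitting yields proper submodels and a sane threshold", {
  set.seed(2)
  samp <- c(rnorm(5e5, 60, 10), rnorm(5e5, 160, 15))
  h <- hist_from_samples(samp)
  sub <- split_classes(fit_lcdg(h))
  expect_equal(sum(sub$p0), 1)
  expect_equal(sum(sub$p1), 1)
  expect_true(all(sub$p0 >= 0) && all(sub$p1 >= 0))
  # oracle: exhaustive misclassification scan over the generating mixture
  d0 <- discrete_gaussian(60, 10); d1 <- discrete_gaussian(160, 15)
  err <- vapply(0:255, function(t)
    0.5 * sum(d0[(0:255) > t]) + 0.5 * sum(d1[(0:255) <= t]), 0)
  t_opt <- which.min(err) - 1L
  expect_true(sub$threshold >= 90 && sub$threshold <= 130)
  expect_lt(abs(sub$threshold - t_opt), 12)
  # symmetric classes around 128 cross at the midpoint
  hs <- 0.5 * discrete_gaussian(100, 12) + 0.5 * discrete_gaussian(156, 12)
  hs <- structure(hs, class = "gray_histogram", n = 1e5, q_levels = 256L)
  ss <- split_classes(fit_lcdg(hs))
  expect_lte(abs(ss$threshold - 128), 1)
})

test_that("class likelihoods behave as conditional distributions", {
  set.seed(3)
  samp <- c(rnorm(2e5, 60, 10), rnorm(2e5, 160, 15))
  sub <- split_classes(fit_lcdg(hist_from_samples(samp)))
  expect_gt(class_likelihood(sub, 160, 1), class_likelihood(sub, 160, 0))
  expect_gt(class_likelihood(sub, 60, 0), class_likelihood(sub, 60, 1))
  expect_equal(sum(class_likelihood(sub, 0:255, 0)), 1)
  expect_equal(sum(class_likelihood(sub, 0:255, 1)), 1)
  expect_error(class_likelihood(sub, 300, 1), "range")
  # spike submodel: probability 1 at the spike
  hsp <- numeric(256); hsp[11] <- 0.6; hsp[241] <- 0.4
  hsp <- structure(hsp, class = "gray_histogram", n = 100, q_levels = 256L)
  ssp <- split_classes(fit_dominant(hsp))
  # at the sigma floor (0.5) the spike's mass concentrates within +/- 1 level
  expect_identical(which.max(ssp$p0) - 1L, 10L)
  expect_gt(sum(class_likelihood(ssp, 9:11, 0)), 0.99)
  expect_lt(class_likelihood(ssp, 100, 0), 1e-6)
})
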