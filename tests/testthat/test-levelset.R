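# Signed distance, curvature, guidance arithmetic, and level-set evolution.

test_that("signed distance follows the positive-inside convention", {
  # centered single-voxel object: zero there, negative elsewhere
  one <- array(0L, c(7, 7, 7)); one[4, 4, 4] <- 1L
  ls1 <- signed_distance(region_map(one))
  expect_identical(ls1$phi[4, 4, 4], 0)
  expect_true(all(ls1$phi[-172] < 0))  # 172 = linear index of (4,4,4)
  # sphere: phi at the center is about the radius
  sph <- sphere_mask(c(41L, 41L, 41L), 12)
  ls <- signed_distance(sph)
  expect_lt(abs(ls$phi[21, 21, 21] - 12), 1)
  expect_true(all((ls$phi >= 0) == (sph$labels == 1L)))
  expect_error(signed_distance(region_map(array(1L, c(4, 4, 4)))),
               "single-label")
})

test_that("signed distance matches all-pairs brute force on small maps", {
  set.seed(8)
  for (k in 1:3) {
    m <- random_map(c(8L, 8L, 8L), 0.3)
    if (sum(m$labels) %in% c(0L, length(m$labels))) next
    expect_equal(signed_distance(m)$phi, brute_signed_distance(m),
                 tolerance = 1e-10)
  }
})

test_that("mean curvature matches closed forms and flips with orientation", {
  sph <- sphere_mask(c(41L, 41L, 41L), 10)
  ls <- signed_distance(sph)
  kap <- mean_curvature(ls)
  g <- kidneyseg:::coord_grids(c(41L, 41L, 41L))
  d <- sqrt((g$x - 21)^2 + (g$y - 21)^2 + (g$z - 21)^2)
  band <- abs(ls$phi) < 1.5 & array(d > 3, dim(kap))
  expect_equal(mean(kap[band]), 2 / 10, tolerance = 0.15)
  neg <- ls; neg$phi <- -ls$phi
  expect_equal(mean(mean_curvature(neg)[band]), -mean(kap[band]),
               tolerance = 1e-10)
  # planar interface: zero curvature
  pl <- region_map(array(g$x <= 20, c(41L, 41L, 41L)))
  lsp <- signed_distance(pl)
  expect_lt(max(abs(mean_curvature(lsp)[abs(lsp$phi) < 1.2])), 1e-10)
})

test_that("guidance combines the three probability factors correctly", {
  dm <- c(3L, 3L, 3L)
  v <- volume(array(100L, dm), quantize = FALSE)
  sub <- list(p0 = rep(0, 256), p1 = rep(0, 256), priors = c(`0` = .5, `1` = .5),
              threshold = 128L, threshold_fallback = FALSE, q_levels = 256L)
  class(sub) <- "lcdg_submodels"
  # frozen worked example: Pr(q|1)=0.8, PrV(1)=0.9, Prsp(1)=0.75, Pr(q|0)=0.2
  sub$p1[101] <- 0.8; sub$p0[101] <- 0.2
  prior <- structure(list(pr1 = array(0.75, dm), spacing = c(1, 1, 1)),
                     class = "shape_prior")
  m <- region_map(array(c(0L, 1L), dm))
  fam <- default_families()
  V <- estimate_potentials(config_frequencies(
    region_map(array(c(0L, 1L), c(8, 8, 8))), fam))
  gd <- guidance(v, m, prior, sub, V, fam)
  prV1 <- spatial_probability_field(m, V, fam)
  om_kd <- 0.8 * prV1 * 0.75
  om_bg <- 0.2 * (1 - prV1) * 0.25
  expect_equal(gd$pr1, om_kd / (om_kd + om_bg), tolerance = 1e-12)
  i <- which.max(abs(prV1 - 0.9) < 0.2)[1]
  # plug-in values with PrV exactly 0.9 (frozen arithmetic)
  expect_equal(0.8 * 0.9 * 0.75 / (0.8 * 0.9 * 0.75 + 0.2 * 0.1 * 0.25),
               0.9908257, tolerance = 1e-6)
  # normalization and the Eq-10 case split everywhere
  expect_true(all(gd$theta[gd$pr1 > 0.5] == -gd$pr1[gd$pr1 > 0.5]))
  expect_true(all(gd$theta[gd$pr1 <= 0.5] == 1 - gd$pr1[gd$pr1 <= 0.5]))
  expect_true(all(abs(gd$theta) <= 1))
  # all factors 0.5 for both classes: the tie goes to the background pull
  sub2 <- sub; sub2$p1[101] <- 0.5; sub2$p0[101] <- 0.5
  prior2 <- structure(list(pr1 = array(0.5, dm), spacing = c(1, 1, 1)),
                      class = "shape_prior")
  V0 <- V; for (i in seq_along(V0$families)) V0$families[[i]]$V[] <- 0
  gd2 <- guidance(v, m, prior2, sub2, V0, fam)
  expect_true(all(gd2$pr1 == 0.5))
  expect_true(all(gd2$theta == 0.5))
  # zero-likelihood voxel: both omegas vanish -> 0.5 / +0.5 default
  sub3 <- sub; sub3$p1[101] <- 0; sub3$p0[101] <- 0
  gd3 <- guidance(v, m, prior, sub3, V, fam)
  expect_true(all(gd3$pr1 == 0.5) && all(gd3$theta == 0.5))
})

test_that("bayes initial map reduces to its factors in limiting cases", {
  co <- tiny_cohort()
  v <- co$subjects[[1]]$series$volumes[[1]]
  sub <- split_classes(fit_lcdg(build_histogram(v)))
  # uniform prior: pure LCDG likelihood-ratio classification
  up <- uniform_prior(v$dims, v$spacing)
  m1 <- bayes_initial_map(v, up, sub)
  lr <- sub$p1[v$data + 1L] > sub$p0[v$data + 1L]
  expect_identical(m1$labels, array(lr + 0L, v$dims))
  # hard prior: the map equals the prior's support
  ball <- sphere_mask(v$dims, 8)
  hp <- structure(list(pr1 = array(as.numeric(ball$labels), v$dims),
                       spacing = v$spacing), class = "shape_prior")
  m2 <- bayes_initial_map(v, hp, sub)
  expect_identical(m2$labels, ball$labels)
})

test_that("evolution expands under uniform kidney pull and stays stable", {
  sph <- sphere_mask(c(41L, 41L, 41L), 8)
  phi <- signed_distance(sph)
  gd <- structure(list(pr1 = array(0.9, c(41, 41, 41)),
                       theta = array(-0.9, c(41, 41, 41)), kappa = NULL),
                  class = "guidance_field")
  sizes <- sum(sph$labels)
  for (k in 1:3) {
    phi <- evolve(phi, gd, n_max = 15L, patience = 999L)
    sizes <- c(sizes, sum(level_set_mask(phi)$labels))
  }
  expect_true(all(diff(sizes) > 0))  # monotone expansion
  expect_true(all(is.finite(phi$phi)))
})

test_that("evolution converges to truth from exact guidance", {
  # noise-free phantom, probabilities painted from the ground truth
  spec <- phantom_spec(dims = c(32L, 32L, 32L), b_values = 0,
                       n_subjects = 3L, seed = 31L, noise_sigma = 0,
                       bias_amplitude = 0)
  s <- generate_subject(spec, 1L)
  tr <- s$truth
  pr1 <- array(ifelse(tr$labels == 1L, 0.95, 0.05), tr$dims)
  gd <- structure(list(pr1 = pr1, theta = ifelse(pr1 > 0.5, -pr1, 1 - pr1),
                       kappa = NULL), class = "guidance_field")
  # start from a 2-voxel dilated truth
  grown <- region_map(
    kidneyseg:::distance_to_set(kidneyseg:::boundary_voxels(tr$labels),
                                tr$spacing) <= 2 * min(tr$spacing) |
      tr$labels == 1L, tr$spacing)
  phi <- evolve(signed_distance(grown), gd, n_max = 200L)
  expect_gte(dsc(level_set_mask(phi), tr), 0.98)
  # uniform background pull makes the object all but vanish
  small <- sphere_mask(c(21L, 21L, 21L), 3)
  gd_bg <- structure(list(pr1 = array(0.05, c(21, 21, 21)),
                          theta = array(0.95, c(21, 21, 21)), kappa = NULL),
                     class = "guidance_field")
  shrunk <- evolve(signed_distance(small), gd_bg, n_max = 100L,
                   band_width = 20, patience = 999L)
  expect_lte(sum(level_set_mask(shrunk)$labels), 2L)
})
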