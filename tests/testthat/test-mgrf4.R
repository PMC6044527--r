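# 4th-order MGRF: clique families, configuration frequencies, analytic
# potentials, energies, conditional probabilities, and the Gibbs sampler.

test_that("the default family set covers the 26-neighborhood", {
  fam <- default_families()
  ords <- vapply(fam, `[[`, 0L, "order")
  expect_equal(sum(ords == 2L), 13L)
  expect_equal(sum(ords == 3L), 13L)
  expect_equal(sum(ords == 4L), 9L)
  for (f in fam) {
    expect_equal(nrow(f$offsets), f$order)
    expect_true(all(abs(f$offsets) <= 1L))
    if (f$order == 3L) {   # collinear: middle is the midpoint of the ends
      expect_equal(f$offsets[2, ], c(0L, 0L, 0L))
      expect_equal(f$offsets[1, ], -f$offsets[3, ])
    }
  }
  expect_identical(fam, default_families())  # deterministic ordering
})

test_that("configuration frequencies match closed-form cases", {
  fam <- default_families()
  ones <- region_map(array(1L, c(8, 8, 8)))
  fr <- config_frequencies(ones, fam)
  for (f in fr) expect_equal(unname(f$freq[1]), 1)  # eq/eq3/eq4 all 1
  # 3D checkerboard: axis pairs all unequal, face diagonals all equal
  g <- expand.grid(x = 1:12, y = 1:12, z = 1:12)
  chk <- region_map(array((g$x + g$y + g$z) %% 2L, c(12, 12, 12)))
  frc <- config_frequencies(chk, fam)
  expect_equal(unname(frc[["p01"]]$freq["eq"]), 0)   # axis (1,0,0)
  expect_equal(unname(frc[["p04"]]$freq["eq"]), 1)   # face diagonal
  expect_error(config_frequencies(array(2L, c(4, 4, 4)), fam), "binary")
  expect_error(config_frequencies(region_map(array(0:1, c(2, 4, 8))), fam),
               ">= 3")
})

test_that("i.i.d. maps sit at the equiprobable baselines", {
  set.seed(10)
  m <- random_map(c(48L, 48L, 48L))
  fr <- config_frequencies(m, patterns = TRUE)
  for (f in fr) {
    expect_equal(sum(f$freq), 1)
    base <- 1 / 2^f$order
    expect_equal(unname(f$pattern_freq), rep(base, 2^f$order),
                 tolerance = 0.06)
  }
})

test_that("analytic potentials match the closed forms", {
  fam <- default_families()
  # checkerboard: V2:eq = 4(0 - 1/2) = -2, V3:eq3 = (16/3)(0 - 1/4) = -4/3
  g <- expand.grid(x = 1:12, y = 1:12, z = 1:12)
  chk <- region_map(array((g$x + g$y + g$z) %% 2L, c(12, 12, 12)))
  V <- estimate_potentials(config_frequencies(chk, fam))
  expect_equal(unname(V$families[[1]]$V), c(-2, 2))
  expect_equal(unname(V$families[[14]]$V["eq3"]), -4 / 3)
  # antisymmetry identities hold exactly for every family
  for (f in V$families) {
    if (f$order == 2L) expect_identical(f$V[["ne"]], -f$V[["eq"]])
    if (f$order == 3L) expect_identical(f$V[["eq2"]], -f$V[["eq3"]])
  }
  # frozen quadruple worked example (independent arithmetic of the
  # closed-form estimator): F_eq4 = 0, F_eq3 = 0, F_eq2 = 1
  fr1 <- structure(list(list(id = "q", order = 4L, n = 100L,
                             freq = c(eq4 = 0, eq3 = 0, eq2 = 1),
                             counts = c(eq4 = 0, eq3 = 0, eq2 = 100))),
                   class = "config_frequencies")
  V1 <- estimate_potentials(fr1)
  expect_equal(V1$lambda, 2688 / 638, tolerance = 1e-12)
  expect_equal(unname(V1$families[[1]]$V),
               c(-0.5266458, -2.1065831, 2.6332288), tolerance = 1e-6)
  # all baselines -> all potentials zero, lambda* = 0
  fr0 <- structure(list(list(id = "q", order = 4L, n = 16L,
                             freq = c(eq4 = 1 / 8, eq3 = 1 / 2, eq2 = 3 / 8),
                             counts = c(eq4 = 2, eq3 = 8, eq2 = 6))),
                   class = "config_frequencies")
  V0 <- estimate_potentials(fr0)
  expect_identical(V0$lambda, 0)
  expect_true(all(unlist(lapply(V0$families, `[[`, "V")) == 0))
})

test_that("energy and conditionals match brute-force enumeration", {
  fam <- default_families()
  set.seed(20)
  base <- random_map(c(16L, 16L, 16L), 0.4)
  V <- estimate_potentials(config_frequencies(base, fam))
  for (k in 1:3) {
    m <- random_map(c(4L, 4L, 4L))
    expect_equal(gibbs_energy(m, V, fam), brute_gibbs_energy(m, V, fam),
                 tolerance = 1e-12)
    p <- c(sample(4, 1), sample(4, 1), sample(4, 1))
    pr1 <- spatial_label_probability(m, V, p, 1L, fam)
    expect_equal(pr1, brute_conditional_pr1(m, V, p, fam),
                 tolerance = 1e-12)
    expect_equal(spatial_label_probability(m, V, p, 0L, fam), 1 - pr1)
  }
  # zero potentials: energy 0, conditionals exactly 1/2
  V0 <- V
  for (i in seq_along(V0$families)) V0$families[[i]]$V[] <- 0
  m <- random_map(c(5L, 5L, 5L))
  expect_identical(gibbs_energy(m, V0, fam), 0)
  expect_true(all(spatial_probability_field(m, V0, fam) == 0.5))
  # locality: flipping one voxel changes the energy by the local difference
  m1 <- m$labels; p <- c(3L, 3L, 3L)
  m1[p[1], p[2], p[3]] <- 1L - m1[p[1], p[2], p[3]]
  en <- kidneyseg:::local_label_energy(m$labels, V, fam)
  local_delta <- (en$E1 - en$E0)[p[1], p[2], p[3]]
  sgn <- if (m$labels[p[1], p[2], p[3]] == 0L) 1 else -1
  expect_equal(gibbs_energy(m1, V, fam) - gibbs_energy(m$labels, V, fam),
               sgn * local_delta, tolerance = 1e-10)
})

test_that("the Gibbs sampler respects the potentials it is given", {
  fam <- default_families()
  set.seed(30)
  base <- random_map(c(16L, 16L, 16L))
  V0 <- estimate_potentials(config_frequencies(base, fam))
  for (i in seq_along(V0$families)) V0$families[[i]]$V[] <- 0
  # zero potentials: i.i.d. fair labels
  s0 <- gibbs_sample(V0, c(32L, 32L, 32L), n_sweeps = 50L, seed = 1L,
                     families = fam)
  expect_gt(mean(s0$labels), 0.45)
  expect_lt(mean(s0$labels), 0.55)
  # determinism under a fixed seed
  s0b <- gibbs_sample(V0, c(32L, 32L, 32L), n_sweeps = 50L, seed = 1L,
                      families = fam)
  expect_identical(s0$labels, s0b$labels)
  # attractive pair potentials raise the equality frequencies
  Va <- V0
  for (i in 1:13) Va$families[[i]]$V <- c(eq = 0.4, ne = -0.4)
  sa <- gibbs_sample(Va, c(24L, 24L, 24L), n_sweeps = 30L, seed = 2L,
                     families = fam)
  fra <- config_frequencies(sa, fam)
  expect_gt(unname(fra[["p01"]]$freq["eq"]), 0.5)
  # estimation recovers the attraction sign across seeded runs
  signs <- vapply(1:10, function(sd) {
    s <- gibbs_sample(Va, c(16L, 16L, 16L), n_sweeps = 20L, seed = sd,
                      families = fam)
    Ve <- estimate_potentials(config_frequencies(s, fam))
    sign(Ve$families[[1]]$V[["eq"]])
  }, 0)
  expect_true(all(signs > 0))
})
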