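# Reference selection, nonrigid registration, shape database construction
# and the appearance-adaptive prior.

test_that("reference selection maximizes NCC and is intensity-invariant", {
  co <- tiny_cohort()
  vols <- lapply(co$subjects, function(s) s$series$volumes[[1]])
  sel <- select_reference(vols, vols[[2]])
  expect_identical(as.integer(sel), 2L)       # identical volume: NCC = 1
  expect_equal(max(attr(sel, "ncc")), 1)
  # NCC is invariant to affine intensity rescaling
  resc <- volume(quantize_grays(vols[[2]]$data * 3 + 40, 1024L),
                 vols[[2]]$spacing, 1024L, quantize = FALSE)
  sel2 <- select_reference(vols, resc)
  expect_identical(as.integer(sel2), 2L)
  expect_gt(attr(sel2, "ncc")[2], 0.999)
  expect_error(select_reference(list(), vols[[1]]), "empty")
})

test_that("a noisier rescan of the same anatomy is matched to itself", {
  # oracle: the generating deformation parameters; subject 2 re-simulated
  # with different noise shares its anatomy draw
  spec <- phantom_spec(dims = c(32L, 32L, 32L), b_values = 0,
                       n_subjects = 5L, seed = 21L)
  co <- generate_cohort(spec)
  spec2 <- spec; spec2$noise_sigma <- 14
  test <- generate_subject(spec2, 2L)
  sel <- select_reference(lapply(co$subjects, function(s)
    s$series$volumes[[1]]), test$series$volumes[[1]])
  expect_identical(as.integer(sel), 2L)
})

test_that("registration is SSD-non-increasing and recovers translations", {
  co <- tiny_cohort()
  v <- co$subjects[[1]]$series$volumes[[1]]
  # moving = fixed: identity wins
  reg0 <- register_nonrigid(v, v)
  expect_equal(reg0$ssd_trace[length(reg0$ssd_trace)], 0)
  expect_lt(max(abs(c(reg0$field$ux, reg0$field$uy, reg0$field$uz))), 0.1)
  # known 3-voxel translation: moving[p] = fixed[p + 3e_x] so u_x = -3
  shifted <- kidneyseg:::shift_array(v$data, c(3L, 0L, 0L), 0L)
  vm <- volume(shifted, v$spacing, quantize = FALSE)
  reg <- register_nonrigid(vm, v)
  inside <- co$subjects[[1]]$truth$labels == 1L
  expect_lt(abs(mean(reg$field$ux[inside]) + 3), 0.5)
  expect_true(all(diff(reg$ssd_trace) <= 1e-9))
  ssd_id <- sum((as.numeric(vm$data) / 255 - as.numeric(v$data) / 255)^2)
  expect_lte(reg$ssd_trace[length(reg$ssd_trace)], ssd_id)
})

test_that("the shape database stays binary and aligned", {
  co <- tiny_cohort()
  tr <- lapply(co$subjects[1:2], function(s)
    list(volume = s$series$volumes[[1]], map = s$truth))
  # two identical training subjects: aligned maps equal the originals
  tr2 <- list(tr[[1]], tr[[1]])
  db2 <- build_shape_database(tr2, 1L)
  expect_identical(db2$maps[[2]]$labels, tr2[[1]]$map$labels)
  db <- build_shape_database(tr, 1L)
  for (m in db$maps) expect_true(all(m$labels %in% c(0L, 1L)))
  expect_gte(dsc(db$maps[[2]], tr[[1]]$map), dsc(tr[[2]]$map, tr[[1]]$map))
  expect_error(build_shape_database(tr[1], 1L), "at least 2")
})

test_that("the window search computes label relative occurrences", {
  # controlled database on an identity field: intensities designed so the
  # window growth and fallback paths are all exercised
  dm <- c(9L, 9L, 9L)
  mkvol <- function(val) volume(array(val, dm), quantize = FALSE)
  kid <- array(0L, dm); kid[4:6, 4:6, 4:6] <- 1L
  db <- structure(list(
    reference_id = 1L,
    volumes = list(mkvol(100L), mkvol(100L), mkvol(100L), mkvol(200L)),
    maps = list(region_map(kid), region_map(kid), region_map(kid),
                region_map(array(0L, dm))),
    fields = NULL, dims = dm, spacing = c(1, 1, 1)),
    class = "shape_database")
  test <- mkvol(100L)
  id <- identity_field(dm)
  pr <- adapt_shape_prior(test, db, field = id, intensity_tol = 10L)
  # voxels match the three kidney-labelled subjects only -> Pr = 1 inside
  expect_equal(pr$pr1[5, 5, 5], 1)
  expect_equal(pr$pr1[1, 1, 1], 0)
  # matches split 3 kidney / 1 background -> 0.75
  db$volumes[[4]] <- mkvol(100L)
  pr2 <- adapt_shape_prior(test, db, field = id, intensity_tol = 10L)
  expect_equal(pr2$pr1[5, 5, 5], 0.75)
  # no match at the initial window but a match after growth
  v3 <- array(0L, dm); v3[1, 1, 1] <- 100L
  db3 <- db
  db3$volumes <- list(mkvol(0L), volume(v3, quantize = FALSE))
  db3$maps <- list(region_map(array(1L, dm)), region_map(array(1L, dm)))
  test3 <- mkvol(100L)
  pr3 <- adapt_shape_prior(test3, db3, field = id, intensity_tol = 5L,
                           window0 = c(3L, 3L, 3L),
                           max_window = c(7L, 7L, 7L))
  expect_equal(pr3$pr1[3, 3, 3], 1)   # found the (1,1,1) voxel after growing
  # far from it, the largest window has no match: occurrence fallback
  expect_equal(pr3$pr1[9, 9, 9], 1)
  expect_error(adapt_shape_prior(test, db, field = id,
                                 window0 = c(2L, 3L, 3L)), "odd")
})

test_that("priors are proper probabilities and deterministic", {
  co <- tiny_cohort()
  tr <- lapply(co$subjects[2:3], function(s)
    list(volume = s$series$volumes[[1]], map = s$truth))
  db <- build_shape_database(tr, 1L)
  test <- co$subjects[[1]]$series$volumes[[1]]
  fld <- coalign_test(test, db)
  p1 <- adapt_shape_prior(test, db, field = fld)
  p2 <- adapt_shape_prior(test, db, field = fld)
  expect_identical(p1$pr1, p2$pr1)
  expect_true(all(p1$pr1 >= 0 & p1$pr1 <= 1))
})
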