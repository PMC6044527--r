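# Appearance-adaptive probabilistic shape prior: a database of co-aligned
# training volumes and kidney maps, plus per-voxel kidney probabilities
# adapted to a test image by intensity-matched adaptive window search.

#' Select the reference subject by normalized cross-correlation
#'
#' After rigid pre-alignment of intensity centroids (integer shift), the
#' candidate with the highest normalized cross-correlation (Pearson
#' correlation of overlapping voxels, invariant to affine intensity
#' rescaling) against the test volume is chosen; ties break to the lowest
#' index.
#'
#' @param candidates list of [volume()]s.
#' @param test a [volume()].
#' @return integer index of the selected candidate, with attribute `ncc`
#'   (all scores).
#' @export
select_reference <- function(candidates, test) {
  if (length(candidates) == 0L) stop("empty candidate list")
  scores <- vapply(candidates, function(cand) {
    stopifnot_same_lattice(cand, test, "candidate and test volumes")
    sh <- round(intensity_centroid(test$data) - intensity_centroid(cand$data))
    shifted <- shift_array(cand$data, as.integer(sh), fill = NA)
    keep <- !is.na(shifted)
    a <- as.numeric(shifted[keep]); b <- as.numeric(test$data[keep])
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(-Inf)
    stats::cor(a, b)
  }, 0)
  best <- which.max(scores)  # which.max takes the first (lowest index) tie
  structure(as.integer(best), ncc = scores)
}

intensity_centroid <- function(arr) {
  g <- coord_grids(dim(arr))
  w <- as.numeric(arr)
  s <- sum(w)
  if (s == 0) return(c(0, 0, 0))
  c(sum(g$x * w), sum(g$y * w), sum(g$z * w)) / s
}

#' Build the co-aligned shape database
#'
#' Every non-reference training subject is registered to the reference
#' subject's (preprocessed) baseline volume with [register_nonrigid()]; its
#' kidney map is warped with nearest-neighbor interpolation so labels stay
#' binary. Training inputs are expected to be preprocessed already.
#'
#' @param training list of subjects, each a list with `volume` (baseline
#'   b = 0 [volume()]) and `map` ([region_map()]).
#' @param reference_id index of the reference subject in `training`.
#' @param config config list (registration settings), see [default_config()].
#' @return object of class `shape_database`: `reference_id`, `volumes`
#'   (aligned), `maps` (aligned, binary), `fields` (reference-to-subject
#'   deformation fields; identity for the reference), `dims`, `spacing`.
#' @export
build_shape_database <- function(training, reference_id = 1L,
                                 config = default_config()) {
  if (length(training) < 2L) stop("need at least 2 training subjects")
  ref <- training[[reference_id]]
  rg <- config$register
  vols <- maps <- fields <- vector("list", length(training))
  for (i in seq_along(training)) {
    if (i == reference_id) {
      vols[[i]] <- ref$volume
      maps[[i]] <- ref$map
      fields[[i]] <- identity_field(ref$volume$dims, ref$volume$spacing)
      next
    }
    stopifnot_same_lattice(training[[i]]$volume, ref$volume,
                           "training volumes")
    reg <- register_nonrigid(training[[i]]$volume, ref$volume,
                             levels = rg$levels, iters = rg$iters,
                             sigma_field_mm = rg$sigma_field_mm)
    vols[[i]] <- reg$warped
    maps[[i]] <- warp(training[[i]]$map, reg$field)
    fields[[i]] <- reg$field
  }
  structure(list(reference_id = as.integer(reference_id), volumes = vols,
                 maps = maps, fields = fields, dims = ref$volume$dims,
                 spacing = ref$volume$spacing),
            class = "shape_database")
}

#' @export
print.shape_database <- function(x, ...) {
  cat(sprintf("<shape_database> %d aligned subjects on a %d x %d x %d lattice (reference #%d)\n",
              length(x$volumes), x$dims[1], x$dims[2], x$dims[3],
              x$reference_id))
  invisible(x)
}

#' Co-align a test volume with the shape database
#'
#' Registers the database reference (moving) onto the test volume (fixed),
#' yielding the deformation field that relates each test voxel to the
#' database lattice (Algorithm step "use the co-aligning deformation field").
#'
#' @param test preprocessed test [volume()].
#' @param db a `shape_database`.
#' @param config config list.
#' @return a `deformation_field` on the test lattice mapping into the
#'   database lattice.
#' @export
coalign_test <- function(test, db, config = default_config()) {
  rg <- config$register
  reg <- register_nonrigid(db$volumes[[db$reference_id]], test,
                           levels = rg$levels, iters = rg$iters,
                           sigma_field_mm = rg$sigma_field_mm)
  reg$field
}

#' Adapt the shape prior to a test volume
#'
#' For every test voxel: map it through the co-aligning deformation field
#' (nearest-voxel rounding), search a window centered at the mapped database
#' location, across all aligned training volumes, for voxels whose intensity
#' is within `intensity_tol` gray levels of the test voxel's; if none match,
#' grow the window by 2 per axis up to `max_window` and repeat. The kidney
#' probability is the relative occurrence of the kidney label among the
#' matched voxels. If the largest window still has no intensity match, the
#' label occurrences in that window are used ignoring intensity (guaranteed
#' fallback).
#'
#' @param test preprocessed test [volume()].
#' @param db a `shape_database`.
#' @param field optional `deformation_field` from [coalign_test()]; computed
#'   when missing.
#' @param window0 odd-sized initial window (default 3 x 3 x 3).
#' @param intensity_tol intensity match tolerance, gray levels (default 10).
#' @param max_window largest window (default 11 x 11 x 11).
#' @param config config list (used when `field` must be computed).
#' @return object of class `shape_prior`: `pr1` (array of kidney
#'   probabilities on the test lattice), `spacing`.
#' @export
adapt_shape_prior <- function(test, db, field = NULL,
                              window0 = c(3L, 3L, 3L), intensity_tol = 10L,
                              max_window = c(11L, 11L, 11L),
                              config = default_config()) {
  stopifnot(inherits(test, "dwi_volume"), inherits(db, "shape_database"))
  if (any(window0 %% 2L != 1L)) stop("window0 must be odd-sized")
  if (is.null(field)) field <- coalign_test(test, db, config)
  g <- coord_grids(test$dims)
  mx <- pmin(pmax(round(g$x + as.vector(field$ux)), 1L), db$dims[1])
  my <- pmin(pmax(round(g$y + as.vector(field$uy)), 1L), db$dims[2])
  mz <- pmin(pmax(round(g$z + as.vector(field$uz)), 1L), db$dims[3])
  pr1 <- adapt_prior_cpp(as.integer(test$data), as.integer(test$dims),
                         cbind(as.integer(mx - 1L), as.integer(my - 1L),
                               as.integer(mz - 1L)),
                         lapply(db$volumes, function(v) as.integer(v$data)),
                         lapply(db$maps, function(m) as.integer(m$labels)),
                         as.integer(db$dims), as.integer(window0),
                         as.integer(max_window), as.integer(intensity_tol))
  structure(list(pr1 = array(pr1, test$dims), spacing = test$spacing,
                 field = field),
            class = "shape_prior")
}

#' Uniform (uninformative) shape prior
#'
#' `Pr_sp:p(1) = 0.5` everywhere; used by the no-shape-prior ablation.
#' @param dims lattice dims.
#' @param spacing voxel spacing.
#' @return a `shape_prior`.
#' @export
uniform_prior <- function(dims, spacing = c(1, 1, 1)) {
  structure(list(pr1 = array(0.5, dims), spacing = spacing),
            class = "shape_prior")
}

#' @export
print.shape_prior <- function(x, ...) {
  cat(sprintf("<shape_prior> %d x %d x %d lattice, mean Pr(kidney) = %.3f\n",
              dim(x$pr1)[1], dim(x$pr1)[2], dim(x$pr1)[3], mean(x$pr1)))
  invisible(x)
}
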