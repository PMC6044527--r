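# Per-b-value segmentation and full-series orchestration: LCDG fit, shape
# prior application, Bayes initial map, analytic potential estimation from
# the initial map, joint guidance, and level-set evolution.

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("[", stage, "] ", conditionMessage(e), call. = FALSE))
}

#' Segment a single b-value volume
#'
#' Runs the full per-scan pipeline on a preprocessed volume: (1) fit the
#' LCDG appearance model to the scan's marginal; (2) take the adapted shape
#' prior; (3) form the Bayes initial map from shape and intensity; (4)
#' estimate the 4th-order Gibbs potentials analytically from the initial
#' map; (5) build the joint guidance field; (6) evolve the level set from
#' the initial map's signed distance. The `mgrf_order = 2` ablation keeps
#' only pair potentials; `use_shape_prior = FALSE` replaces the prior with
#' the uniform field.
#'
#' @param v preprocessed [volume()] of one b-value scan.
#' @param prior a `shape_prior` adapted from the subject's baseline scan.
#' @param config config list, see [default_config()].
#' @return object of class `segmentation_result`: `mask` ([region_map()]),
#'   `initial_mask`, `model` (LCDG), `potentials`, `iterations`,
#'   `converged`.
#' @export
segment_bvalue <- function(v, prior, config = default_config()) {
  stopifnot(inherits(v, "dwi_volume"))
  cfg <- config
  fams <- default_families()
  if (!isTRUE(cfg$shape$enabled))
    prior <- uniform_prior(v$dims, v$spacing)
  model <- with_stage("lcdg", fit_lcdg(
    build_histogram(v), max_subordinate = cfg$lcdg$max_subordinate,
    tol = cfg$lcdg$tol, kidney_brighter = cfg$lcdg$kidney_brighter))
  submodels <- with_stage("lcdg", split_classes(model))
  m_ini <- with_stage("bayes_map", bayes_initial_map(v, prior, submodels))
  if (sum(m_ini$labels) == 0L || sum(m_ini$labels) == length(m_ini$labels))
    stop("[bayes_map] initial map is single-label; cannot segment")
  V <- with_stage("mgrf", {
    pot <- estimate_potentials(config_frequencies(m_ini, fams))
    if (cfg$mgrf$order == 2L) {
      for (i in seq_along(pot$families))
        if (pot$families[[i]]$order > 2L)
          pot$families[[i]]$V[] <- 0
    }
    pot
  })
  guide <- with_stage("guidance",
                      guidance(v, m_ini, prior, submodels, V, fams))
  phi0 <- with_stage("levelset", signed_distance(m_ini))
  lsc <- cfg$levelset
  phi <- with_stage("levelset", evolve(
    phi0, guide, n_max = lsc$n_max, tau = lsc$tau,
    band_width = lsc$band_width, convergence_tol = lsc$convergence_tol,
    reinit_every = lsc$reinit_every, patience = lsc$patience))
  structure(list(mask = level_set_mask(phi), initial_mask = m_ini,
                 model = model, potentials = V,
                 iterations = attr(phi, "iterations"),
                 converged = attr(phi, "converged")),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %d kidney voxels, %d iterations%s\n",
              sum(x$mask$labels), x$iterations,
              if (isTRUE(x$converged)) " (converged)" else ""))
  invisible(x)
}

#' Segment a full multi-b-value series
#'
#' One shape prior is adapted from the subject's baseline (b = 0) scan and
#' reused for every b-value; the LCDG appearance model and the MGRF spatial
#' model are re-fitted per scan. Volumes are preprocessed according to the
#' config before modelling.
#'
#' @param series a [dwi_series()] containing a b = 0 scan.
#' @param db a `shape_database` built from baseline training scans.
#' @param config config list.
#' @return list with `results` (one `segmentation_result` per b-value,
#'   named by b), `prior` (the shared `shape_prior`), `b_values`.
#' @export
segment_series <- function(series, db, config = default_config()) {
  stopifnot(inherits(series, "dwi_series"))
  if (series$b_values[1] != 0)
    stop("series must contain a b = 0 baseline scan for the shape prior")
  pre <- lapply(series$volumes, preprocess_volume, config = config)
  prior <- if (isTRUE(config$shape$enabled)) {
    adapt_shape_prior(pre[[1]], db,
                      window0 = config$shape$window0,
                      intensity_tol = config$shape$intensity_tol,
                      max_window = config$shape$max_window, config = config)
  } else uniform_prior(series$volumes[[1]]$dims, series$volumes[[1]]$spacing)
  results <- lapply(pre, segment_bvalue, prior = prior, config = config)
  names(results) <- paste0("b", series$b_values)
  list(results = results, prior = prior, b_values = series$b_values)
}
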