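# Synthetic multi-subject, multi-b-value kidney phantom generator. Each
# subject is a bean-shaped kidney (deformed ellipsoid with a hilum notch)
# with a cortex shell and medulla interior, embedded in an inhomogeneous
# background; signals follow the mono-exponential decay
# S_b = S0 * exp(-b * ADC) per tissue, corrupted by a smooth multiplicative
# bias field and Rician noise. Per-subject random smooth deformations model
# inter-subject anatomical variability.

#' Phantom specification
#'
#' Defaults emulate the DW-MRI acquisition the package targets: 1.28 x 1.28
#' mm in-plane resolution with 4 mm sections, the twelve protocol b-values,
#' and signal-to-noise degrading with b. ADCs are in mm^2/s; `background`
#' entries give the range (ADC) and the per-blob levels (S0) of the mixed
#' abdominal background. All randomness is fixed by `seed`.
#'
#' @param dims lattice dims (default 48^3).
#' @param spacing voxel size mm (default c(1.28, 1.28, 4)).
#' @param b_values diffusion weightings, s/mm^2 (default
#'   [protocol_b_values()]).
#' @param adc list: `cortex`, `medulla`, `organ` scalars and `background`
#'   range (min, max), mm^2/s. `organ` is the liver/spleen-like structure
#'   abutting the kidney.
#' @param s0 list: `cortex`, `medulla`, `organ` scalars and `background`
#'   blob levels.
#' @param noise_sigma Rician noise sigma in gray levels (default 8).
#' @param bias_amplitude peak relative amplitude of the multiplicative bias
#'   field (default 0.2; 0 disables).
#' @param deform_amplitude_mm RMS amplitude of the per-subject smooth
#'   deformation (default 5).
#' @param cortex_thickness_mm cortex shell thickness (default 6).
#' @param n_subjects cohort size (default 8).
#' @param seed integer seed fixing all randomness.
#' @param q_levels gray levels (default 256).
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(dims = c(48L, 48L, 48L), spacing = c(1.28, 1.28, 4),
                         b_values = protocol_b_values(),
                         adc = list(cortex = 2.0e-3, medulla = 1.8e-3,
                                    organ = 1.4e-3,
                                    background = c(1.0e-3, 2.5e-3)),
                         s0 = list(cortex = 170, medulla = 145, organ = 160,
                                   background = c(70, 95, 120)),
                         noise_sigma = 8, bias_amplitude = 0.2,
                         deform_amplitude_mm = 5, cortex_thickness_mm = 6,
                         n_subjects = 8L, seed = 1L, q_levels = 256L) {
  stopifnot(adc$cortex > 0, adc$medulla > 0, adc$organ > 0,
            all(adc$background > 0),
            all(spacing > 0), all(diff(sort(b_values)) > 0))
  structure(list(dims = as.integer(dims), spacing = spacing,
                 b_values = sort(b_values), adc = adc, s0 = s0,
                 noise_sigma = noise_sigma, bias_amplitude = bias_amplitude,
                 deform_amplitude_mm = deform_amplitude_mm,
                 cortex_thickness_mm = cortex_thickness_mm,
                 n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 q_levels = as.integer(q_levels)),
            class = "phantom_spec")
}

subject_seed <- function(spec, subject_index) {
  as.integer((abs(spec$seed) + 7919 * subject_index) %% 2147483647)
}

# smooth unit-RMS random field
smooth_noise <- function(dm, sigma_vox) {
  n <- array(stats::rnorm(prod(dm)), dm)
  s <- gaussian_smooth3(n, sigma_vox)
  s / max(stats::sd(s), 1e-12)
}

#' Generate one phantom subject
#'
#' Builds the subject's deformed kidney geometry and ground-truth map, then
#' simulates every b-value volume: tissue-wise mono-exponential decay,
#' multiplicative bias (when enabled), Rician noise (when `noise_sigma > 0`)
#' and quantization to `{0..Q-1}`. Deterministic given the spec seed and
#' subject index.
#'
#' @param spec a [phantom_spec()].
#' @param subject_index positive integer.
#' @return list with `series` ([dwi_series()]), `truth` ([region_map()]),
#'   `cortex`, `medulla` (masks), `bias` (the simulated field), and
#'   `params` (the subject's deformation draws).
#' @export
generate_subject <- function(spec, subject_index = 1L) {
  dm <- spec$dims; sp <- spec$spacing
  # the background tissue layout is shared anatomy: one cohort-level
  # pattern, deformed per subject below (real abdomens agree across
  # subjects up to deformation; a per-subject random background would not)
  set.seed(spec$seed)
  blob_base <- smooth_noise(dm, 10 / sp)
  set.seed(subject_seed(spec, subject_index))
  half_mm <- dm * sp / 2
  semi <- pmin(c(24, 27, 48), 0.8 * half_mm)
  if (any(semi < 2 * spec$cortex_thickness_mm))
    stop("dims too small for the kidney shape at this spacing")
  # mm coordinates of voxel centers, origin at volume center
  g <- coord_grids(dm)
  xm <- (g$x - (dm[1] + 1) / 2) * sp[1]
  ym <- (g$y - (dm[2] + 1) / 2) * sp[2]
  zm <- (g$z - (dm[3] + 1) / 2) * sp[3]
  # per-subject pose and smooth deformation
  scale <- stats::runif(3, 0.92, 1.08)
  trans <- c(stats::runif(2, -4, 4), stats::runif(1, -8, 8))
  amp <- spec$deform_amplitude_mm / sqrt(3)
  dx <- smooth_noise(dm, 15 / sp) * amp
  dy <- smooth_noise(dm, 15 / sp) * amp
  dz <- smooth_noise(dm, 15 / sp) * amp
  xs <- (xm - trans[1] + as.vector(dx)) / scale[1]
  ys <- (ym - trans[2] + as.vector(dy)) / scale[2]
  zs <- (zm - trans[3] + as.vector(dz)) / scale[3]
  inside <- (xs / semi[1])^2 + (ys / semi[2])^2 + (zs / semi[3])^2 <= 1
  # hilum notch: a ball bitten out of the +y face midline
  notch_c <- c(0, semi[2], 0)
  notch_r <- 0.35 * semi[2]
  notch <- ((xs - notch_c[1])^2 + (ys - notch_c[2])^2 +
            (zs - notch_c[3])^2) <= notch_r^2
  kidney <- array(inside & !notch, dm)
  if (sum(kidney) < 100L) stop("dims too small for the kidney shape")
  truth <- region_map(kidney, sp)
  # cortex shell / medulla interior via interior Euclidean depth
  depth <- distance_to_set(boundary_voxels(truth$labels), sp)
  medulla <- kidney & (depth > spec$cortex_thickness_mm)
  cortex <- kidney & !medulla
  # mixed background tissue blobs: sample the shared pattern at the
  # subject's deformed coordinates so the background moves with the anatomy
  gx <- (xs + dm[1] * sp[1] / 2) / sp[1] + 0.5
  gy <- (ys + dm[2] * sp[2] / 2) / sp[2] + 0.5
  gz <- (zs + dm[3] * sp[3] / 2) / sp[3] + 0.5
  # 30% of the background variance is subject-specific (fat distribution,
  # bowel contents, ...) and is not explained by any deformation
  blob <- 0.7 * array(trilinear_sample(blob_base, gx, gy, gz), dm) +
          0.3 * smooth_noise(dm, 10 / sp)
  qs <- stats::quantile(blob[!kidney], c(1 / 3, 2 / 3))
  bg_class <- array(1L + (blob > qs[1]) + (blob > qs[2]), dm)
  adc_bg <- seq(spec$adc$background[1], spec$adc$background[2], length.out = 3)
  s0_map <- array(spec$s0$background[bg_class], dm)
  adc_map <- array(adc_bg[bg_class], dm)
  # adjacent organ (liver/spleen-like): abuts the kidney on the -y side
  # with near-kidney intensity, the main low-contrast challenge
  org_c <- c(0, -(semi[2] + 0.8 * 0.55 * semi[2]), 0)
  org_s <- c(0.8 * semi[1], 0.55 * semi[2], 0.7 * semi[3])
  organ <- array(((xs - org_c[1]) / org_s[1])^2 +
                 ((ys - org_c[2]) / org_s[2])^2 +
                 ((zs - org_c[3]) / org_s[3])^2 <= 1, dm) & !kidney
  s0_map[organ] <- spec$s0$organ; adc_map[organ] <- spec$adc$organ
  s0_map[cortex] <- spec$s0$cortex;  adc_map[cortex] <- spec$adc$cortex
  s0_map[medulla] <- spec$s0$medulla; adc_map[medulla] <- spec$adc$medulla
  # smooth multiplicative bias field, mean 1, peak deviation bias_amplitude
  bias <- array(1, dm)
  if (spec$bias_amplitude > 0) {
    bn <- smooth_noise(dm, 25 / sp)
    bias <- 1 + spec$bias_amplitude * bn / max(abs(bn))
    bias <- bias / mean(bias)
  }
  vols <- lapply(spec$b_values, function(b) {
    s <- s0_map * exp(-b * adc_map) * bias
    if (spec$noise_sigma > 0) {
      n1 <- array(stats::rnorm(prod(dm), 0, spec$noise_sigma), dm)
      n2 <- array(stats::rnorm(prod(dm), 0, spec$noise_sigma), dm)
      s <- sqrt((s + n1)^2 + n2^2)
    }
    volume(pmin(pmax(round(s), 0), spec$q_levels - 1L), sp, spec$q_levels,
           quantize = FALSE)
  })
  series <- dwi_series(spec$b_values, vols,
                       subject_id = sprintf("phantom%02d", subject_index))
  list(series = series, truth = truth,
       cortex = region_map(cortex, sp), medulla = region_map(medulla, sp),
       bias = bias,
       params = list(scale = scale, trans = trans))
}

#' Generate a phantom cohort
#'
#' @param spec a [phantom_spec()] with `n_subjects >= 3`.
#' @return object of class `phantom_cohort`: list of subjects (each as
#'   returned by [generate_subject()]) with the spec attached.
#' @export
generate_cohort <- function(spec = phantom_spec()) {
  if (spec$n_subjects < 3L) stop("need n_subjects >= 3")
  subjects <- lapply(seq_len(spec$n_subjects),
                     function(i) generate_subject(spec, i))
  structure(list(subjects = subjects, spec = spec),
            class = "phantom_cohort")
}

#' Leave-one-subject-out folds
#'
#' @param cohort a `phantom_cohort` (or anything with `$subjects`).
#' @return list of folds, each `list(test = i, train = setdiff(...))`.
#' @export
leave_one_out <- function(cohort) {
  n <- length(cohort$subjects)
  lapply(seq_len(n), function(i) list(test = i, train = setdiff(seq_len(n), i)))
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d subjects, %d b-values, %d x %d x %d voxels\n",
              length(x$subjects), length(x$spec$b_values),
              x$spec$dims[1], x$spec$dims[2], x$spec$dims[3]))
  invisible(x)
}
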