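# Preprocessing: non-parametric bias-field correction and global histogram
# equalization, applied per b-value volume before any modelling.

#' Correct low-frequency intensity inhomogeneity
#'
#' Estimates a smooth multiplicative bias field in the log domain by
#' iterative low-pass residual fitting: at each iteration the low-frequency
#' component of the (log) residual is extracted with a Gaussian kernel of
#' physical scale `smoothness_mm` and accumulated into the field estimate.
#' Zero-intensity voxels carry no weight in the estimation (mask-normalized
#' smoothing), but receive an extrapolated field value. The returned field is
#' normalized to mean 1, so the corrected volume keeps the global intensity
#' scale.
#'
#' @param v a [volume()].
#' @param smoothness_mm physical scale (mm) of the bias field; variation
#'   below this scale is treated as anatomy, above it as bias. Default 40.
#' @param max_iter maximum number of low-pass refinement iterations.
#' @param tol stop when the largest log-field update falls below this.
#' @return list with `volume` (corrected, re-quantized) and `field`
#'   (multiplicative bias estimate, class `bias_field`).
#' @export
correct_bias <- function(v, smoothness_mm = 40, max_iter = 3, tol = 1e-3) {
  stopifnot(inherits(v, "dwi_volume"))
  g <- v$data
  dm <- dim(g)
  unit <- structure(array(1, dm), class = "bias_field", spacing = v$spacing)
  if (max(g) == 0L)  # all-zero volume: nothing to correct
    return(list(volume = v, field = unit))
  w <- array(as.numeric(g > 0), dm)
  L <- array(0, dm)
  L[g > 0] <- log(g[g > 0])
  # the field is low-frequency by assumption, so estimate it on a coarser
  # grid (factor 2) and upsample; this is exact up to the smoothing scale
  coarse <- min(dm) >= 24L
  if (coarse) {
    nd <- pmax(ceiling(dm / 2), 4L)
    gr <- coord_grids(nd)
    sc <- (dm - 1) / pmax(nd - 1, 1L)
    cx <- 1 + (gr$x - 1) * sc[1]; cy <- 1 + (gr$y - 1) * sc[2]
    cz <- 1 + (gr$z - 1) * sc[3]
    Lw <- array(trilinear_sample(L * w, cx, cy, cz), nd)
    wc <- array(trilinear_sample(w, cx, cy, cz), nd)
    Lc <- array(ifelse(wc > 1e-6, Lw / pmax(wc, 1e-6), 0), nd)
    sigma_vox <- smoothness_mm / (v$spacing * sc)
  } else {
    Lc <- L; wc <- w
    sigma_vox <- smoothness_mm / v$spacing
  }
  bias_log_c <- array(0, dim(Lc))
  for (iter in seq_len(max_iter)) {
    resid <- Lc - bias_log_c
    resid_c <- resid - stats::weighted.mean(resid, wc)
    low <- gaussian_smooth3(resid_c, sigma_vox, weights = wc)
    bias_log_c <- bias_log_c + low
    if (max(abs(low)) < tol) break
  }
  bias_log <- if (coarse) {
    gf <- coord_grids(dm)
    nd <- dim(bias_log_c)
    sc <- (nd - 1) / pmax(dm - 1, 1L)
    array(trilinear_sample(bias_log_c, 1 + (gf$x - 1) * sc[1],
                           1 + (gf$y - 1) * sc[2], 1 + (gf$z - 1) * sc[3]),
          dm)
  } else bias_log_c
  field <- exp(bias_log)
  field <- field / mean(field)
  corrected <- g / field
  corrected <- pmin(pmax(round(corrected), 0), v$q_levels - 1L)
  out <- volume(corrected, v$spacing, v$q_levels, quantize = FALSE)
  list(volume = out,
       field = structure(field, class = "bias_field", spacing = v$spacing))
}

#' Global histogram equalization
#'
#' Remaps gray levels by the midpoint empirical CDF,
#' `q -> round((Q-1) * (CDF(q) - h(q)/2))`: the mapping is monotone
#' non-decreasing, preserves level sets, and maps an already-uniform
#' histogram to the identity up to quantization.
#'
#' @param v a [volume()].
#' @return equalized [volume()].
#' @export
equalize_histogram <- function(v) {
  stopifnot(inherits(v, "dwi_volume"))
  Q <- v$q_levels
  h <- tabulate(v$data + 1L, nbins = Q) / length(v$data)
  cdf_mid <- cumsum(h) - h / 2
  lut <- as.integer(round((Q - 1L) * cdf_mid))
  lut <- cummax(lut)  # guard monotonicity under rounding
  out <- array(lut[v$data + 1L], dim(v$data))
  volume(out, v$spacing, Q, quantize = FALSE)
}

#' Standard preprocessing for one volume
#'
#' Bias correction followed by global histogram equalization (either stage
#' can be disabled via the config, see [default_config()]).
#'
#' @param v a [volume()].
#' @param config a config list as from [default_config()].
#' @return preprocessed [volume()].
#' @export
preprocess_volume <- function(v, config = default_config()) {
  pp <- config$preprocess
  if (isTRUE(pp$bias_enabled))
    v <- correct_bias(v, pp$bias_smoothness_mm, pp$bias_max_iter)$volume
  if (isTRUE(pp$equalize_enabled))
    v <- equalize_histogram(v)
  v
}
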