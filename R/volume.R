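#' 3D gray-level volume
#'
#' A `dwi_volume` holds a 3D integer grid of gray levels on a finite lattice
#' with voxel spacing in mm. Gray levels live in `{0, ..., q_levels - 1}`;
#' inputs are quantized to this range on construction (see [quantize_grays()]).
#'
#' @param data 3D numeric/integer array of voxel values.
#' @param spacing Numeric length-3, voxel size (mm) along x, y, z.
#' @param q_levels Number of gray levels Q (default 256).
#' @param quantize If `TRUE` (default) rescale/clip `data` into
#'   `{0..q_levels-1}` by the contract of [quantize_grays()]; if `FALSE`,
#'   `data` must already be integral and in range.
#' @return A `dwi_volume` object.
#' @export
volume <- function(data, spacing = c(1, 1, 1), q_levels = 256L, quantize = TRUE) {
  if (length(dim(data)) != 3L)
    stop("volume data must be a 3D array, got ", length(dim(data)), " dims")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values")
  q_levels <- as.integer(q_levels)
  if (quantize) {
    data <- quantize_grays(data, q_levels)
  } else {
    if (any(data != round(data)) || min(data) < 0 || max(data) > q_levels - 1L)
      stop("data not integral in {0..Q-1}; use quantize = TRUE")
    storage.mode(data) <- "integer"
  }
  structure(list(data = data, dims = dim(data), spacing = spacing,
                 q_levels = q_levels),
            class = "dwi_volume")
}

#' Quantize voxel values onto {0..Q-1}
#'
#' Integral inputs already inside `[0, Q-1]` are kept verbatim; anything else
#' (floating point values, or out-of-range integers) is mapped linearly so
#' that the input minimum goes to 0 and the maximum to Q-1, then rounded.
#' A constant out-of-range input maps to all zeros.
#'
#' @param data numeric array.
#' @param q_levels number of gray levels Q.
#' @return integer array with the same dimensions.
#' @export
quantize_grays <- function(data, q_levels = 256L) {
  q_levels <- as.integer(q_levels)
  data <- array(as.vector(data), dim(data))  # strip foreign classes/attrs
  rng <- range(data)
  integral <- all(data == round(data))
  if (integral && rng[1] >= 0 && rng[2] <= q_levels - 1L) {
    storage.mode(data) <- "integer"
    return(data)
  }
  if (rng[2] > rng[1]) {
    data <- (data - rng[1]) / (rng[2] - rng[1]) * (q_levels - 1L)
  } else {
    data <- data * 0
  }
  data <- round(data)
  storage.mode(data) <- "integer"
  data
}

#' Binary kidney/background region map
#'
#' Labels take values in L = {0, 1} (0 background, 1 kidney) over the same
#' lattice as the associated volume.
#'
#' @param labels 3D array of 0/1 (or logical).
#' @param spacing voxel size (mm).
#' @return A `dwi_region_map` object.
#' @export
region_map <- function(labels, spacing = c(1, 1, 1)) {
  if (length(dim(labels)) != 3L) stop("region map must be a 3D array")
  if (is.logical(labels)) labels <- labels + 0L
  if (!all(labels %in% c(0L, 1L))) stop("region map labels must be in {0, 1}")
  storage.mode(labels) <- "integer"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("invalid spacing")
  structure(list(labels = labels, dims = dim(labels), spacing = spacing),
            class = "dwi_region_map")
}

#' Multi-b-value DW-MRI series
#'
#' One [volume()] per diffusion weighting, b-values strictly increasing, all
#' volumes sharing dims and spacing.
#'
#' @param b_values numeric vector of b-values (s/mm^2), non-negative.
#' @param volumes list of `dwi_volume`, one per b-value.
#' @param subject_id subject identifier.
#' @return A `dwi_series` object.
#' @export
dwi_series <- function(b_values, volumes, subject_id = "subject") {
  b_values <- as.numeric(b_values)
  if (length(b_values) != length(volumes))
    stop("one volume per b-value required")
  if (any(b_values < 0)) stop("b-values must be non-negative")
  ord <- order(b_values)
  b_values <- b_values[ord]; volumes <- volumes[ord]
  if (any(diff(b_values) <= 0))
    stop("duplicate b-value entries in series: b-values must be strictly increasing")
  d0 <- volumes[[1]]$dims; s0 <- volumes[[1]]$spacing
  for (v in volumes) {
    if (!inherits(v, "dwi_volume")) stop("volumes must be dwi_volume objects")
    if (!identical(v$dims, d0) || !isTRUE(all.equal(v$spacing, s0)))
      stop("all volumes in a series must share dims and spacing")
  }
  structure(list(b_values = b_values, volumes = volumes,
                 subject_id = subject_id),
            class = "dwi_series")
}

#' The default DW-MRI acquisition b-values
#'
#' The twelve diffusion weightings of the acquisition protocol the package
#' defaults emulate: 0, 50, 100, 200, ..., 1000 s/mm^2.
#' @return numeric vector of length 12.
#' @export
protocol_b_values <- function() {
  c(0, 50, 100, 200, 300, 400, 500, 600, 700, 800, 900, 1000)
}

#' @export
print.dwi_volume <- function(x, ...) {
  cat(sprintf("<dwi_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, Q = %d\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3], x$q_levels))
  invisible(x)
}

#' @export
print.dwi_region_map <- function(x, ...) {
  cat(sprintf("<dwi_region_map> %d x %d x %d voxels, %d kidney voxels\n",
              x$dims[1], x$dims[2], x$dims[3], sum(x$labels)))
  invisible(x)
}

#' @export
print.dwi_series <- function(x, ...) {
  cat(sprintf("<dwi_series> subject '%s', %d b-values: %s\n", x$subject_id,
              length(x$b_values), paste(x$b_values, collapse = ", ")))
  invisible(x)
}

# internal coercions
as_map_volume <- function(m) volume(m$labels, m$spacing, q_levels = 256L,
                                    quantize = FALSE)

stopifnot_same_lattice <- function(a, b, what = "inputs") {
  da <- if (!is.null(a$dims)) a$dims else dim(a)
  db <- if (!is.null(b$dims)) b$dims else dim(b)
  if (!identical(da, db)) stop(what, " must share the same lattice dims")
}
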