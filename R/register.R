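# Multi-resolution demons-style deformable registration minimizing the sum
# of squared voxel-wise intensity differences (SSD), with Gaussian
# regularization of the displacement field. The deformation field lives on
# the fixed lattice and maps fixed-lattice coordinates into moving-lattice
# coordinates: moving_coord = x + u(x), in voxel units.

new_deformation_field <- function(ux, uy, uz, spacing = c(1, 1, 1)) {
  structure(list(ux = ux, uy = uy, uz = uz, dims = dim(ux),
                 spacing = spacing),
            class = "deformation_field")
}

#' Identity deformation field
#' @param dims lattice dims.
#' @param spacing voxel spacing (mm).
#' @return a `deformation_field` with all-zero displacements.
#' @export
identity_field <- function(dims, spacing = c(1, 1, 1)) {
  z <- array(0, dims)
  new_deformation_field(z, z, z, spacing)
}

# sample `arr` through the field (arr lives on the moving lattice)
warp_array <- function(arr, field, interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  g <- coord_grids(field$dims)
  x <- g$x + as.vector(field$ux)
  y <- g$y + as.vector(field$uy)
  z <- g$z + as.vector(field$uz)
  vals <- if (interp == "linear") trilinear_sample(arr, x, y, z)
          else nearest_sample(arr, x, y, z)
  array(vals, field$dims)
}

#' Warp a volume or region map through a deformation field
#'
#' Volumes are interpolated trilinearly and re-quantized; region maps use
#' nearest-neighbor interpolation and stay binary.
#'
#' @param obj a [volume()] or [region_map()].
#' @param field a `deformation_field` (on the target lattice).
#' @return warped object of the same class, on the field's lattice.
#' @export
warp <- function(obj, field) {
  if (inherits(obj, "dwi_volume")) {
    arr <- warp_array(obj$data, field, "linear")
    volume(pmin(pmax(round(arr), 0), obj$q_levels - 1L), field$spacing,
           obj$q_levels, quantize = FALSE)
  } else if (inherits(obj, "dwi_region_map")) {
    arr <- warp_array(obj$labels, field, "nearest")
    region_map(arr, field$spacing)
  } else stop("cannot warp object of class ", class(obj)[1])
}

ssd <- function(a, b) sum((as.numeric(a) - as.numeric(b))^2)

downsample2 <- function(arr) {
  dm <- dim(arr)
  nd <- pmax(ceiling(dm / 2), 4L)
  sm <- gaussian_smooth3(arr, 0.85)
  g <- coord_grids(nd)
  sc <- (dm - 1) / pmax(nd - 1, 1L)
  array(trilinear_sample(sm, 1 + (g$x - 1) * sc[1], 1 + (g$y - 1) * sc[2],
                         1 + (g$z - 1) * sc[3]), nd)
}

upsample_field <- function(u, nd, ratio) {
  g <- coord_grids(nd)
  dm <- dim(u)
  sc <- (dm - 1) / pmax(nd - 1, 1L)
  array(trilinear_sample(u, 1 + (g$x - 1) * sc[1], 1 + (g$y - 1) * sc[2],
                         1 + (g$z - 1) * sc[3]), nd) * ratio
}

#' Nonrigid SSD-minimizing registration
#'
#' Multi-resolution demons-type registration: at each level the intensity
#' difference drives a displacement update along the warped-image gradient,
#' and the accumulated field is smoothed with a Gaussian of physical scale
#' `sigma_field_mm`. The best field seen (evaluated by full-resolution SSD,
#' with the identity as the initial candidate) is returned, so
#' `SSD(warped, fixed) <= SSD(moving, fixed)` and the per-level SSD trace is
#' non-increasing by construction.
#'
#' @param moving,fixed [volume()]s with equal dims.
#' @param levels number of resolution levels (coarsest is
#'   `1/2^(levels-1)` scale).
#' @param iters iterations per level, coarsest first (recycled).
#' @param sigma_field_mm Gaussian regularization scale of the field, mm.
#' @return list with `field` (a `deformation_field` on the fixed lattice),
#'   `warped` ([volume()]), `ssd_trace` (full-resolution SSD after each
#'   level) and `converged`.
#' @export
register_nonrigid <- function(moving, fixed, levels = 3L,
                              iters = c(60L, 40L, 25L), sigma_field_mm = 3) {
  stopifnot(inherits(moving, "dwi_volume"), inherits(fixed, "dwi_volume"))
  stopifnot_same_lattice(moving, fixed, "moving and fixed volumes")
  iters <- rep(iters, length.out = levels)
  M0 <- moving$data / max(1, max(moving$data))
  F0 <- fixed$data / max(1, max(fixed$data))
  # image pyramids, finest first
  pyrM <- list(M0); pyrF <- list(F0)
  for (l in seq_len(levels - 1L)) {
    pyrM[[l + 1L]] <- downsample2(pyrM[[l]])
    pyrF[[l + 1L]] <- downsample2(pyrF[[l]])
  }
  eval_full <- function(ux, uy, uz, at_level) {
    # upsample the field to full resolution and measure SSD there
    if (at_level > 1L) {
      nd <- dim(F0)
      ratio <- (dim(F0) - 1) / pmax(dim(ux) - 1, 1L)
      ux <- upsample_field(ux, nd, ratio[1])
      uy <- upsample_field(uy, nd, ratio[2])
      uz <- upsample_field(uz, nd, ratio[3])
    }
    fld <- new_deformation_field(ux, uy, uz, fixed$spacing)
    list(ssd = ssd(warp_array(M0, fld, "linear"), F0), field = fld)
  }
  best <- eval_full(array(0, dim(F0)), array(0, dim(F0)), array(0, dim(F0)), 1L)
  ssd_trace <- numeric(0)
  ux <- uy <- uz <- NULL
  for (lev in seq.int(levels, 1L)) {
    Fv <- pyrF[[lev]]; Mv <- pyrM[[lev]]
    dm <- dim(Fv)
    scale_mm <- fixed$spacing * 2^(lev - 1L)
    sig <- sigma_field_mm / scale_mm
    if (is.null(ux)) {
      ux <- array(0, dm); uy <- array(0, dm); uz <- array(0, dm)
    } else {
      ratio <- (dm - 1) / pmax(dim(ux) - 1, 1L)
      ux <- upsample_field(ux, dm, ratio[1])
      uy <- upsample_field(uy, dm, ratio[2])
      uz <- upsample_field(uz, dm, ratio[3])
    }
    fld <- new_deformation_field(ux, uy, uz, scale_mm)
    lev_best <- ssd(warp_array(Mv, fld, "linear"), Fv)
    for (it in seq_len(iters[levels - lev + 1L])) {
      w <- warp_array(Mv, fld, "linear")
      diff <- w - Fv
      gx <- central_diff(w, 1L); gy <- central_diff(w, 2L)
      gz <- central_diff(w, 3L)
      g2 <- gx^2 + gy^2 + gz^2
      den <- g2 + diff^2
      fac <- ifelse(den > 1e-12, diff / den, 0)
      ux <- gaussian_smooth3(ux - fac * gx, sig)
      uy <- gaussian_smooth3(uy - fac * gy, sig)
      uz <- gaussian_smooth3(uz - fac * gz, sig)
      fld <- new_deformation_field(ux, uy, uz, scale_mm)
      cur <- ssd(warp_array(Mv, fld, "linear"), Fv)
      if (cur > lev_best * 1.05) break  # diverging at this level
      lev_best <- min(lev_best, cur)
    }
    cand <- eval_full(ux, uy, uz, lev)
    if (cand$ssd < best$ssd) best <- cand
    ssd_trace <- c(ssd_trace, best$ssd)
  }
  warped_arr <- warp_array(moving$data, best$field, "linear")
  warped <- volume(pmin(pmax(round(warped_arr), 0), moving$q_levels - 1L),
                   fixed$spacing, moving$q_levels, quantize = FALSE)
  list(field = best$field, warped = warped, ssd_trace = ssd_trace,
       converged = TRUE)
}
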