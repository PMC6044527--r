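# Geometric deformable boundary: signed distance fields (positive inside,
# zero on the boundary, negative outside), mean curvature, the joint
# appearance/spatial/shape guidance field, and the upwind level-set
# evolution.

new_level_set <- function(phi, spacing, n = 0L) {
  structure(list(phi = phi, spacing = spacing, n = n), class = "level_set")
}

boundary_voxels <- function(labels) {
  # object voxels with >= 1 in-lattice background 6-neighbor; an object
  # clipped by the lattice face has no surface there
  obj <- labels == 1L
  nb <- shift_array(labels, c(1L, 0L, 0L), 1L) &
        shift_array(labels, c(-1L, 0L, 0L), 1L) &
        shift_array(labels, c(0L, 1L, 0L), 1L) &
        shift_array(labels, c(0L, -1L, 0L), 1L) &
        shift_array(labels, c(0L, 0L, 1L), 1L) &
        shift_array(labels, c(0L, 0L, -1L), 1L)
  obj & !nb
}

#' Signed distance map of a region map
#'
#' `Phi(p) = +d(p, B)` strictly inside the boundary, `0` on boundary voxels,
#' `-d(p, B)` outside, with `B` the set of object voxels having a background
#' 6-neighbor, and `d` the Euclidean distance (mm, respecting spacing).
#'
#' @param m a [region_map()] with at least one voxel of each label.
#' @return a `level_set` object (field `phi` in mm).
#' @export
signed_distance <- function(m) {
  stopifnot(inherits(m, "dwi_region_map"))
  n1 <- sum(m$labels)
  if (n1 == 0L || n1 == length(m$labels))
    stop("signed distance undefined for a single-label map")
  B <- boundary_voxels(m$labels)
  d <- distance_to_set(B, m$spacing)
  phi <- ifelse(m$labels == 1L, d, -d)
  new_level_set(array(phi, m$dims), m$spacing)
}

#' Zero-level mask of a level-set field
#'
#' Voxels with `phi >= 0` (inside or on the boundary).
#' @param ls a `level_set`.
#' @return a [region_map()].
#' @export
level_set_mask <- function(ls) {
  region_map(ls$phi >= 0, ls$spacing)
}

#' Mean curvature of the zero-level boundary
#'
#' Curvature of the level sets with respect to the *outward* normal
#' (`-grad(Phi)/|grad(Phi)|` under the positive-inside convention), computed
#' by central differences: a sphere of radius r has curvature about `+2/r`
#' on its zero level, a planar interface 0, and negating `Phi` flips the
#' sign. Values are clamped to `1/min(spacing)` in magnitude and set to 0
#' where the gradient is numerically zero.
#'
#' @param ls a `level_set`.
#' @return curvature array (1/mm).
#' @export
mean_curvature <- function(ls) {
  phi <- ls$phi; sp <- ls$spacing
  gx <- central_diff(phi, 1L, sp[1])
  gy <- central_diff(phi, 2L, sp[2])
  gz <- central_diff(phi, 3L, sp[3])
  mag <- sqrt(gx^2 + gy^2 + gz^2)
  eps <- 1e-8
  nx <- ifelse(mag > eps, gx / mag, 0)
  ny <- ifelse(mag > eps, gy / mag, 0)
  nz <- ifelse(mag > eps, gz / mag, 0)
  div <- central_diff(nx, 1L, sp[1]) + central_diff(ny, 2L, sp[2]) +
         central_diff(nz, 3L, sp[3])
  kap <- -div  # outward normal = -grad(Phi)/|grad(Phi)| (positive inside)
  kap[mag <= eps] <- 0
  clamp <- 1 / min(sp)
  pmin(pmax(kap, -clamp), clamp)
}

#' Bayes initial region map from shape and intensity
#'
#' `m_ini(p) = 1` iff
#' `Pr(g_p | 1) * Pr_sp:p(1) > Pr(g_p | 0) * Pr_sp:p(0)`; ties go to
#' background.
#'
#' @param test a [volume()].
#' @param prior a `shape_prior` on the test lattice.
#' @param submodels `lcdg_submodels` from [split_classes()].
#' @return a [region_map()].
#' @export
bayes_initial_map <- function(test, prior, submodels) {
  stopifnot(inherits(test, "dwi_volume"), inherits(prior, "shape_prior"))
  stopifnot_same_lattice(test, list(dims = dim(prior$pr1)),
                         "volume and prior")
  p1 <- submodels$p1[test$data + 1L] * as.vector(prior$pr1)
  p0 <- submodels$p0[test$data + 1L] * as.vector(1 - prior$pr1)
  region_map(array(p1 > p0, test$dims), test$spacing)
}

#' Joint guidance field of the deformable boundary
#'
#' Combines the three voxel-wise probabilities into
#' `Omega_kd:p = Pr(q|1) Pr_V:p(1) Pr_sp:p(1)` and
#' `Omega_bg:p = Pr(q|0) (1 - Pr_V:p(1)) (1 - Pr_sp:p(1))`, normalizes them
#' to `Pr_p(1)` and `Pr_p(0) = 1 - Pr_p(1)`, and derives the evolution
#' magnitude/direction `theta_p = -Pr_p(1)` where `Pr_p(1) > 0.5`, else
#' `+Pr_p(0)`. Where both Omegas vanish, `Pr_p(1) = 0.5` and
#' `theta_p = +0.5` (background pull).
#'
#' @param test a [volume()].
#' @param m current [region_map()] (conditioning map of the spatial model).
#' @param prior a `shape_prior`.
#' @param submodels `lcdg_submodels`.
#' @param V `gibbs_potentials`.
#' @param families `clique_families` matching `V`.
#' @return object of class `guidance_field`: arrays `pr1`, `theta`, `kappa`
#'   (initial curvature of the signed distance of `m`; recomputed during
#'   evolution).
#' @export
guidance <- function(test, m, prior, submodels, V,
                     families = default_families()) {
  prV1 <- spatial_probability_field(m, V, families)
  om_kd <- submodels$p1[test$data + 1L] * as.vector(prV1) *
    as.vector(prior$pr1)
  om_bg <- submodels$p0[test$data + 1L] * as.vector(1 - prV1) *
    as.vector(1 - prior$pr1)
  s <- om_kd + om_bg
  pr1 <- ifelse(s > 0, om_kd / s, 0.5)
  theta <- ifelse(pr1 > 0.5, -pr1, 1 - pr1)
  kap <- mean_curvature(signed_distance(m))
  structure(list(pr1 = array(pr1, test$dims),
                 theta = array(theta, test$dims), kappa = kap),
            class = "guidance_field")
}

#' Evolve the level-set boundary under the guidance field
#'
#' Discrete-time evolution
#' `Phi_{n+1}(p) = Phi_n(p) - tau F_n(p) |grad Phi_n(p)|` with the speed
#' `F_n(p) = kappa(p) theta_p` (curvature recomputed each iteration),
#' Godunov upwind gradient, periodic redistancing, and a narrow band of
#' `band_width` voxels around the zero level. The time step obeys the CFL
#' bound `tau <= 0.45 min(spacing) / max|F_n|` when not given. Evolution
#' stops when the zero-level mask changes fewer than
#' `convergence_tol * mask volume` voxels over `patience` consecutive
#' iterations, or at `n_max`.
#'
#' @param phi a `level_set` (typically from [signed_distance()]).
#' @param guide a `guidance_field`.
#' @param n_max iteration cap.
#' @param tau fixed time step; `NULL` (default) uses the CFL bound per
#'   iteration.
#' @param band_width half-width of the active band, voxels.
#' @param convergence_tol mask-change fraction defining convergence.
#' @param reinit_every redistancing period, iterations.
#' @param patience consecutive quiet iterations required.
#' @return a `level_set` with diagnostics attributes `iterations`,
#'   `mask_changes`, `converged`.
#' @export
evolve <- function(phi, guide, n_max = 200L, tau = NULL, band_width = 6,
                   convergence_tol = 0.001, reinit_every = 20L,
                   patience = 10L) {
  stopifnot(inherits(phi, "level_set"), inherits(guide, "guidance_field"))
  sp <- phi$spacing
  stopifnot_same_lattice(list(dims = dim(phi$phi)),
                         list(dims = dim(guide$theta)),
                         "level set and guidance")
  res <- evolve_cpp(as.numeric(phi$phi), as.numeric(guide$theta),
                    as.integer(dim(phi$phi)), as.numeric(sp),
                    as.integer(n_max),
                    if (is.null(tau)) NA_real_ else as.numeric(tau),
                    band_width * min(sp), convergence_tol,
                    as.integer(reinit_every), as.integer(patience))
  if (res$diverged != 0L)
    stop("level-set evolution diverged at iteration ", res$iterations,
         ": mask ", if (res$diverged == 1L) "emptied" else "flooded",
         " (changes: ", paste(utils::head(res$mask_changes, 20),
                              collapse = ","), ")")
  out <- new_level_set(array(res$phi, dim(phi$phi)), sp, n = res$iterations)
  attr(out, "iterations") <- res$iterations
  attr(out, "mask_changes") <- res$mask_changes
  attr(out, "converged") <- res$converged
  out
}
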