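# Segmentation evaluation: Dice similarity coefficient, 95-percentile
# modified Hausdorff distance, percentage kidney volume difference, and
# cohort summaries with paired t-tests.

#' Dice similarity coefficient
#'
#' `2|A intersect B| / (|A| + |B|)`; 1 when both masks are empty
#' (convention). Symmetric in its arguments.
#'
#' @param a,b [region_map()]s on the same lattice.
#' @return DSC in `[0, 1]`.
#' @export
dsc <- function(a, b) {
  stopifnot_same_lattice(a, b, "masks")
  na <- sum(a$labels); nb <- sum(b$labels)
  if (na + nb == 0L) return(1)
  2 * sum(a$labels & b$labels) / (na + nb)
}

#' 95-percentile modified Hausdorff distance (mm)
#'
#' The 95th percentile of the pooled symmetric surface-to-surface Euclidean
#' distances: every boundary voxel of A to the nearest boundary voxel of B
#' and vice versa, in mm using the voxel spacing. Boundary voxels are object
#' voxels with a background 6-neighbor.
#'
#' @param a,b non-empty [region_map()]s on the same lattice.
#' @param spacing voxel spacing override (defaults to the masks' spacing).
#' @return distance in mm.
#' @export
mhd95 <- function(a, b, spacing = NULL) {
  stopifnot_same_lattice(a, b, "masks")
  if (sum(a$labels) == 0L || sum(b$labels) == 0L)
    stop("mhd95 undefined for an empty mask")
  sp <- if (is.null(spacing)) a$spacing else spacing
  ba <- boundary_voxels(a$labels)
  bb <- boundary_voxels(b$labels)
  da <- distance_to_set(bb, sp)[ba]  # A-surface to nearest B-surface
  db <- distance_to_set(ba, sp)[bb]
  as.numeric(stats::quantile(c(da, db), 0.95, names = FALSE))
}

#' Percentage kidney volume difference
#'
#' `100 |V_seg - V_gt| / V_gt`, volumes in mm^3 (voxel count times voxel
#' volume). Normalized by the ground truth, hence not symmetric.
#'
#' @param seg segmented [region_map()].
#' @param gt non-empty ground-truth [region_map()].
#' @return percentage (>= 0).
#' @export
pkvd <- function(seg, gt) {
  stopifnot_same_lattice(seg, gt, "masks")
  if (sum(gt$labels) == 0L) stop("pkvd undefined for empty ground truth")
  vs <- sum(seg$labels) * prod(seg$spacing)
  vg <- sum(gt$labels) * prod(gt$spacing)
  100 * abs(vs - vg) / vg
}

#' Evaluate a cohort of segmentations
#'
#' Per-subject DSC, MHD95 and PKVD against ground truth, with min / max /
#' mean +/- SD summaries. When a second method's masks are supplied, paired
#' two-sided t-tests compare the two methods per metric (zero-variance
#' differences are flagged with `p = NA`).
#'
#' @param pairs list of subjects, each a list with `seg` and `gt`
#'   ([region_map()]s); optionally named.
#' @param pairs2 optional second method: list of `seg` maps (same subjects,
#'   same order) or of `list(seg=, gt=)`.
#' @return object of class `cohort_evaluation`: `table` (per-subject
#'   data.frame), `summary` (min/max/mean/sd per metric), and `t_tests`
#'   when `pairs2` is given.
#' @export
evaluate_cohort <- function(pairs, pairs2 = NULL) {
  if (length(pairs) < 2L) stop("need >= 2 subjects for cohort summaries")
  one <- function(seg, gt) c(dsc = dsc(seg, gt), mhd95 = mhd95(seg, gt),
                             pkvd = pkvd(seg, gt))
  tab <- t(vapply(pairs, function(p) one(p$seg, p$gt), numeric(3)))
  tab <- as.data.frame(tab)
  tab$subject <- if (!is.null(names(pairs))) names(pairs)
                 else sprintf("s%02d", seq_along(pairs))
  tab <- tab[c("subject", "dsc", "mhd95", "pkvd")]
  summ <- lapply(c(dsc = "dsc", mhd95 = "mhd95", pkvd = "pkvd"), function(mm)
    c(min = min(tab[[mm]]), max = max(tab[[mm]]),
      mean = mean(tab[[mm]]), sd = stats::sd(tab[[mm]])))
  out <- list(table = tab, summary = summ)
  if (!is.null(pairs2)) {
    tab2 <- t(vapply(seq_along(pairs2), function(i) {
      p2 <- pairs2[[i]]
      seg2 <- if (inherits(p2, "dwi_region_map")) p2 else p2$seg
      one(seg2, pairs[[i]]$gt)
    }, numeric(3)))
    tab2 <- as.data.frame(tab2)
    out$table2 <- tab2
    out$t_tests <- lapply(c(dsc = "dsc", mhd95 = "mhd95", pkvd = "pkvd"),
                          function(mm) {
      d <- tab[[mm]] - tab2[[mm]]
      if (stats::sd(d) == 0)
        return(list(p_value = NA_real_, zero_variance = TRUE))
      tt <- stats::t.test(tab[[mm]], tab2[[mm]], paired = TRUE)
      list(p_value = tt$p.value, zero_variance = FALSE)
    })
  }
  structure(out, class = "cohort_evaluation")
}

#' @export
print.cohort_evaluation <- function(x, ...) {
  cat("<cohort_evaluation>\n")
  for (mm in names(x$summary)) {
    s <- x$summary[[mm]]
    cat(sprintf("  %-6s min %.3g  max %.3g  mean %.3g +/- %.3g\n",
                mm, s["min"], s["max"], s["mean"], s["sd"]))
  }
  if (!is.null(x$t_tests))
    for (mm in names(x$t_tests))
      cat(sprintf("  paired t-test (%s): p = %s\n", mm,
                  format(x$t_tests[[mm]]$p_value, digits = 3)))
  invisible(x)
}
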