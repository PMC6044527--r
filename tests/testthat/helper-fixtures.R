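# Shared fixtures and independent (brute-force) oracles used across tests.

# --- small geometric builders ----------------------------------------------

sphere_mask <- function(dims = c(41L, 41L, 41L), radius = 12,
                        center = (dims + 1) / 2, spacing = c(1, 1, 1)) {
  g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                   z = seq_len(dims[3]))
  d <- sqrt(((g$x - center[1]) * spacing[1])^2 +
            ((g$y - center[2]) * spacing[2])^2 +
            ((g$z - center[3]) * spacing[3])^2)
  region_map(array(d <= radius, dims), spacing)
}

random_map <- function(dims, p = 0.5) {
  region_map(array(stats::runif(prod(dims)) < p, dims))
}

# histogram object from raw samples (clipped to the gray range)
hist_from_samples <- function(x, q_levels = 256L) {
  q <- pmin(pmax(round(x), 0), q_levels - 1L)
  h <- tabulate(q + 1L, nbins = q_levels)
  structure(h / sum(h), class = "gray_histogram", n = length(x),
            q_levels = q_levels)
}

# --- brute-force oracles ----------------------------------------------------

# Gibbs energy by naive triple-loop clique enumeration
brute_gibbs_energy <- function(m, V, fams) {
  if (inherits(m, "dwi_region_map")) m <- m$labels
  dm <- dim(m)
  e <- 0
  for (fi in seq_along(fams)) {
    off <- fams[[fi]]$offsets
    nu <- fams[[fi]]$order
    pv <- V$families[[fi]]$V
    for (x in seq_len(dm[1])) for (y in seq_len(dm[2]))
      for (z in seq_len(dm[3])) {
        pos <- cbind(x + off[, 1], y + off[, 2], z + off[, 3])
        if (any(pos < 1L) || any(pos[, 1] > dm[1]) ||
            any(pos[, 2] > dm[2]) || any(pos[, 3] > dm[3])) next
        s <- sum(m[pos])
        e <- e + if (nu == 2L) {
          if (s != 1L) pv[["eq"]] else pv[["ne"]]
        } else if (nu == 3L) {
          if (s == 0L || s == 3L) pv[["eq3"]] else pv[["eq2"]]
        } else {
          if (s == 0L || s == 4L) pv[["eq4"]]
          else if (s == 2L) pv[["eq2"]] else pv[["eq3"]]
        }
      }
  }
  e
}

# conditional label probability by explicit two-state enumeration
brute_conditional_pr1 <- function(m, V, p, fams) {
  if (inherits(m, "dwi_region_map")) m <- m$labels
  m0 <- m; m0[p[1], p[2], p[3]] <- 0L
  m1 <- m; m1[p[1], p[2], p[3]] <- 1L
  d <- brute_gibbs_energy(m1, V, fams) - brute_gibbs_energy(m0, V, fams)
  1 / (1 + exp(-d))
}

# exhaustive nearest-boundary-distance MHD (all-pairs loops)
brute_mhd95 <- function(a, b, spacing = c(1, 1, 1)) {
  surf <- function(m) {
    dm <- dim(m$labels)
    out <- NULL
    for (x in seq_len(dm[1])) for (y in seq_len(dm[2]))
      for (z in seq_len(dm[3])) {
        if (m$labels[x, y, z] != 1L) next
        nb <- FALSE
        for (d in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
                       c(0,0,1), c(0,0,-1))) {
          q <- c(x, y, z) + d
          if (any(q < 1L) || any(q > dm)) next
          if (m$labels[q[1], q[2], q[3]] == 0L) { nb <- TRUE; break }
        }
        if (nb) out <- rbind(out, c(x, y, z))
      }
    out
  }
  sa <- surf(a); sb <- surf(b)
  dists <- function(from, to) {
    apply(from, 1, function(p)
      min(sqrt(colSums((t(to) * spacing - p * spacing)^2))))
  }
  da <- dists(sa, sb); db <- dists(sb, sa)
  as.numeric(stats::quantile(c(da, db), 0.95, names = FALSE))
}

# exhaustive signed distance (all-pairs min distance to boundary voxels)
brute_signed_distance <- function(m) {
  dm <- dim(m$labels)
  bnd <- NULL
  for (x in seq_len(dm[1])) for (y in seq_len(dm[2]))
    for (z in seq_len(dm[3])) {
      if (m$labels[x, y, z] != 1L) next
      is_b <- FALSE
      for (d in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
                     c(0,0,1), c(0,0,-1))) {
        q <- c(x, y, z) + d
        if (any(q < 1L) || any(q > dm)) next
        if (m$labels[q[1], q[2], q[3]] == 0L) { is_b <- TRUE; break }
      }
      if (is_b) bnd <- rbind(bnd, c(x, y, z))
    }
  phi <- array(0, dm)
  for (x in seq_len(dm[1])) for (y in seq_len(dm[2]))
    for (z in seq_len(dm[3])) {
      d <- min(sqrt(colSums((t(bnd) - c(x, y, z))^2)))
      phi[x, y, z] <- if (m$labels[x, y, z] == 1L) d else -d
    }
  phi
}

# small phantom cohort used by several test files (32^3, 3 b-values)
tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- phantom_spec(dims = c(32L, 32L, 32L), b_values = c(0, 500, 1000),
                           n_subjects = 3L, seed = 11L)
      cache <<- generate_cohort(spec)
    }
    cache
  }
})
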