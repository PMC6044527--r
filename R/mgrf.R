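# Fourth-order Markov-Gibbs random field over binary region maps on the
# 26-neighborhood: clique families, empirical label-configuration
# frequencies, analytic potential estimates, Gibbs energies, and voxel-wise
# conditional label probabilities Pr_V:p(l).

# The 13 lexicographically-positive directions of the 26-neighborhood,
# ordered axis / face-diagonal / body-diagonal.
neighbor_directions <- function() {
  ds <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  ds <- ds[!(ds$dx == 0 & ds$dy == 0 & ds$dz == 0), ]
  pos <- apply(ds, 1, function(d) {
    nz <- d[d != 0]
    nz[1] > 0
  })
  ds <- ds[pos, ]
  ds <- ds[order(rowSums(abs(ds)), ds$dx, ds$dy, ds$dz), ]
  unname(as.matrix(ds))
}

#' Default clique families of the 4th-order model
#'
#' 13 pair families (one per distinct direction of the 26-neighborhood), 13
#' collinear triple families (a voxel and both opposite neighbors along each
#' direction), and 9 quadruple families (2x2 squares in the three
#' axis-aligned plane orientations plus the six diagonal-plane 2x2
#' arrangements representable within the 26-neighborhood). Ordering is
#' deterministic; offsets are relative to the anchor voxel and satisfy
#' `max(|dx|,|dy|,|dz|) <= 1`.
#'
#' @return object of class `clique_families`: list of families, each with
#'   `id`, `order` (2, 3 or 4) and an `offsets` matrix (one row per voxel).
#' @export
default_families <- function() {
  dirs <- neighbor_directions()
  fams <- list()
  for (i in seq_len(nrow(dirs)))
    fams[[length(fams) + 1L]] <- list(
      id = sprintf("p%02d", i), order = 2L,
      offsets = rbind(c(0L, 0L, 0L), dirs[i, ]))
  for (i in seq_len(nrow(dirs)))
    fams[[length(fams) + 1L]] <- list(
      id = sprintf("t%02d", i), order = 3L,
      offsets = rbind(-dirs[i, ], c(0L, 0L, 0L), dirs[i, ]))
  ax <- diag(3L)
  k <- 0L
  # axis-aligned 2x2 squares
  for (i in 1:2) for (j in (i + 1):3) {
    k <- k + 1L
    fams[[length(fams) + 1L]] <- list(
      id = sprintf("q%02d", k), order = 4L,
      offsets = rbind(c(0L, 0L, 0L), ax[i, ], ax[j, ], ax[i, ] + ax[j, ]))
  }
  # diagonal-plane 2x2 squares: one axis edge x one perpendicular diagonal
  for (i in 1:3) {
    others <- setdiff(1:3, i)
    for (sgn in c(1L, -1L)) {
      k <- k + 1L
      f <- ax[others[1], ] + sgn * ax[others[2], ]
      fams[[length(fams) + 1L]] <- list(
        id = sprintf("q%02d", k), order = 4L,
        offsets = rbind(c(0L, 0L, 0L), ax[i, ], f, ax[i, ] + f))
    }
  }
  for (i in seq_along(fams)) storage.mode(fams[[i]]$offsets) <- "integer"
  structure(fams, class = "clique_families")
}

#' @export
print.clique_families <- function(x, ...) {
  ords <- vapply(x, `[[`, 0L, "order")
  cat(sprintf("<clique_families> %d families: %d pair, %d triple, %d quadruple\n",
              length(x), sum(ords == 2), sum(ords == 3), sum(ords == 4)))
  invisible(x)
}

# all cliques of a family that fit the lattice, as shifted label arrays
# (list of arrays over anchor positions, NA where the clique leaves R)
family_label_stack <- function(m, offsets) {
  lapply(seq_len(nrow(offsets)),
         function(i) shift_array(m, offsets[i, ], fill = NA))
}

#' Empirical label-configuration frequencies
#'
#' For every clique family, counts the label-equality classes over all
#' cliques fully inside the lattice: pairs `{eq, ne}`; triples
#' `{eq3 = all equal, eq2 = exactly two equal}`; quadruples
#' `{eq4 = all equal, eq3 = exactly three equal, eq2 = two-and-two}`.
#' With `patterns = TRUE` the full per-configuration counts (indexed by the
#' binary label tuple) are included as well.
#'
#' @param m a [region_map()] (or 0/1 array), dims at least 3 per axis.
#' @param families a `clique_families` object.
#' @param patterns also tabulate full label configurations.
#' @return object of class `config_frequencies`: per family, a list with
#'   `order`, `n` (clique count), `freq` (named class frequencies summing to
#'   1), `counts`, and optionally `pattern_freq`.
#' @export
config_frequencies <- function(m, families = default_families(),
                               patterns = FALSE) {
  if (inherits(m, "dwi_region_map")) m <- m$labels
  if (!all(m %in% c(0L, 1L))) stop("region map must be binary")
  if (any(dim(m) < 3L)) stop("map dims must be >= 3 in every axis")
  out <- lapply(families, function(fam) {
    st <- family_label_stack(m, fam$offsets)
    valid <- Reduce(`&`, lapply(st, function(a) !is.na(a)))
    n <- sum(valid)
    labs <- lapply(st, function(a) a[valid])
    ssum <- Reduce(`+`, labs)
    nu <- fam$order
    if (nu == 2L) {
      counts <- c(eq = sum(ssum != 1L), ne = sum(ssum == 1L))
    } else if (nu == 3L) {
      counts <- c(eq3 = sum(ssum == 0L | ssum == 3L),
                  eq2 = sum(ssum == 1L | ssum == 2L))
    } else {
      counts <- c(eq4 = sum(ssum == 0L | ssum == 4L),
                  eq3 = sum(ssum == 1L | ssum == 3L),
                  eq2 = sum(ssum == 2L))
    }
    res <- list(id = fam$id, order = nu, n = n, freq = counts / n,
                counts = counts)
    if (patterns) {
      code <- Reduce(`+`, lapply(seq_along(labs),
                                 function(i) labs[[i]] * 2L^(i - 1L)))
      pc <- tabulate(code + 1L, nbins = 2L^nu)
      names(pc) <- vapply(0:(2L^nu - 1L), function(v)
        paste(rev(as.integer(intToBits(v)[seq_len(nu)])), collapse = ""), "")
      res$pattern_freq <- pc / n
    }
    res
  })
  names(out) <- vapply(families, `[[`, "", "id")
  structure(out, class = "config_frequencies")
}

#' Analytic Gibbs potential estimates
#'
#' Closed-form potential estimates from the empirical equality-class
#' frequencies: for pairs `V2:eq = 4(F_eq - 1/2) = -V2:ne`; for collinear
#' triples `V3:eq3 = (16/3)(F_eq3 - 1/4) = -V3:eq2`; for quadruples the
#' centered frequencies `f4 = F_eq4 - 1/8`, `f3 = F_eq3 - 1/2`,
#' `f2 = F_eq2 - 3/8` are scaled by the shared factor
#' `lambda* = sum(f4^2 + f3^2 + f2^2) / sum(7/64 f4^2 + 1/4 f3^2 + 15/64 f2^2)`
#' (sums over the quadruple families). All offsets are against the
#' equiprobable-label baselines, so an i.i.d. random map yields potentials
#' near 0, and `lambda*` is defined as 0 when every centered frequency is 0.
#'
#' @param freqs a `config_frequencies` object.
#' @return object of class `gibbs_potentials`: per family the potential
#'   values (`eq`/`ne`, `eq3`/`eq2`, or `eq4`/`eq3`/`eq2`), plus the shared
#'   `lambda`.
#' @export
estimate_potentials <- function(freqs) {
  stopifnot(inherits(freqs, "config_frequencies"))
  quad <- Filter(function(f) f$order == 4L, freqs)
  num <- 0; den <- 0
  for (f in quad) {
    fs <- c(f$freq[["eq4"]] - 1 / 8, f$freq[["eq3"]] - 1 / 2,
            f$freq[["eq2"]] - 3 / 8)
    num <- num + sum(fs^2)
    den <- den + 7 / 64 * fs[1]^2 + 1 / 4 * fs[2]^2 + 15 / 64 * fs[3]^2
  }
  lambda <- if (den < 1e-300) 0 else num / den
  pots <- lapply(freqs, function(f) {
    if (f$order == 2L) {
      v <- 4 * (f$freq[["eq"]] - 1 / 2)
      list(id = f$id, order = 2L, V = c(eq = v, ne = -v))
    } else if (f$order == 3L) {
      v <- 16 / 3 * (f$freq[["eq3"]] - 1 / 4)
      list(id = f$id, order = 3L, V = c(eq3 = v, eq2 = -v))
    } else {
      fs <- c(f$freq[["eq4"]] - 1 / 8, f$freq[["eq3"]] - 1 / 2,
              f$freq[["eq2"]] - 3 / 8)
      list(id = f$id, order = 4L,
           V = c(eq4 = lambda * fs[1], eq3 = lambda * fs[2],
                 eq2 = lambda * fs[3]),
           f = c(f4 = fs[1], f3 = fs[2], f2 = fs[3]))
    }
  })
  structure(list(families = pots, lambda = lambda),
            class = "gibbs_potentials")
}

#' @export
print.gibbs_potentials <- function(x, ...) {
  cat(sprintf("<gibbs_potentials> %d families, lambda* = %.4g\n",
              length(x$families), x$lambda))
  invisible(x)
}

# clique potential for a label sum under a family's potential vector
clique_potential <- function(V, nu, ssum) {
  if (nu == 2L) {
    ifelse(ssum != 1L, V[["eq"]], V[["ne"]])
  } else if (nu == 3L) {
    ifelse(ssum == 0L | ssum == 3L, V[["eq3"]], V[["eq2"]])
  } else {
    ifelse(ssum == 0L | ssum == 4L, V[["eq4"]],
           ifelse(ssum == 2L, V[["eq2"]], V[["eq3"]]))
  }
}

#' Unnormalized Gibbs energy of a region map
#'
#' The Gibbs exponent `sum_a sum_{c in C_a} V_a(m on c)` (the partition
#' function is never computed). Cliques extending outside the lattice are
#' skipped.
#'
#' @param m a [region_map()] or 0/1 array.
#' @param V a `gibbs_potentials` object.
#' @param families the matching `clique_families`.
#' @return scalar energy.
#' @export
gibbs_energy <- function(m, V, families = default_families()) {
  freqs <- config_frequencies(m, families)
  e <- 0
  for (i in seq_along(families)) {
    f <- freqs[[i]]; pv <- V$families[[i]]$V
    e <- e + sum(f$counts * pv[names(f$counts)])
  }
  e
}

# local conditional energies: arrays E0, E1 with E_l[p] = sum of potentials
# over all cliques containing p, with m_p replaced by l (others from m).
local_label_energy <- function(m, V, families = default_families()) {
  if (inherits(m, "dwi_region_map")) m <- m$labels
  dm <- dim(m)
  E0 <- array(0, dm); E1 <- array(0, dm)
  for (i in seq_along(families)) {
    fam <- families[[i]]
    pv <- V$families[[i]]$V
    nu <- fam$order
    offs <- fam$offsets
    for (role in seq_len(nu)) {
      # clique anchored so that the role-th member sits at p
      rel <- sweep(offs, 2L, offs[role, ])
      others <- rel[-role, , drop = FALSE]
      st <- lapply(seq_len(nrow(others)),
                   function(j) shift_array(m, others[j, ], fill = NA))
      valid <- Reduce(`&`, lapply(st, function(a) !is.na(a)))
      osum <- Reduce(`+`, lapply(st, function(a) {
        a[is.na(a)] <- 0L
        a
      }))
      for (l in c(0L, 1L)) {
        contrib <- clique_potential(pv, nu, osum + l)
        contrib[!valid] <- 0
        if (l == 0L) E0 <- E0 + contrib else E1 <- E1 + contrib
      }
    }
  }
  list(E0 = E0, E1 = E1)
}

#' Voxel-wise conditional label probabilities of the spatial model
#'
#' `Pr_V:p(l) = exp(E_p(l)) / (exp(E_p(0)) + exp(E_p(1)))` where `E_p(l)`
#' sums the potentials of every clique containing `p` with `m_p` replaced by
#' `l` and all other labels taken from `m`. Returns the full field for
#' label 1 (the label-0 field is its complement).
#'
#' @param m a [region_map()] or 0/1 array.
#' @param V a `gibbs_potentials` object.
#' @param families the matching `clique_families`.
#' @return array of `Pr_V:p(1)` over the lattice.
#' @export
spatial_probability_field <- function(m, V, families = default_families()) {
  en <- local_label_energy(m, V, families)
  d <- en$E1 - en$E0
  1 / (1 + exp(-d))
}

#' Conditional label probability at one voxel
#'
#' @param m a [region_map()] or 0/1 array.
#' @param V a `gibbs_potentials` object.
#' @param p integer length-3 voxel position (1-based).
#' @param l label 0 or 1.
#' @param families the matching `clique_families`.
#' @return `Pr_V:p(l)`.
#' @export
spatial_label_probability <- function(m, V, p, l,
                                      families = default_families()) {
  dm <- if (inherits(m, "dwi_region_map")) m$dims else dim(m)
  if (any(p < 1L) || any(p > dm)) stop("voxel position outside the lattice")
  pr1 <- spatial_probability_field(m, V, families)[p[1], p[2], p[3]]
  if (l == 1L) pr1 else 1 - pr1
}

#' Gibbs sampler for the 4th-order model
#'
#' Sequential single-site Gibbs updates (raster order, x fastest) using the
#' conditional probabilities of [spatial_probability_field()]. Uses R's RNG,
#' so results are reproducible under `set.seed()`; a `seed` argument is
#' provided for convenience.
#'
#' @param V a `gibbs_potentials` object.
#' @param dims lattice dims (each >= 8 recommended).
#' @param n_sweeps full passes over the lattice.
#' @param seed optional integer seed.
#' @param families the matching `clique_families`.
#' @param init optional initial [region_map()] or 0/1 array; default i.i.d.
#'   fair labels.
#' @return a [region_map()].
#' @export
gibbs_sample <- function(V, dims, n_sweeps = 50L, seed = NULL,
                         families = default_families(), init = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dims <- as.integer(dims)
  if (is.null(init)) {
    init <- array(as.integer(stats::runif(prod(dims)) < 0.5), dims)
  } else if (inherits(init, "dwi_region_map")) {
    init <- init$labels
  }
  enc <- lapply(families, function(fam) {
    list(order = fam$order, offsets = fam$offsets)
  })
  pots <- lapply(seq_along(families), function(i) {
    as.numeric(V$families[[i]]$V)
  })
  out <- gibbs_sample_cpp(enc, pots, as.integer(init), dims,
                          as.integer(n_sweeps))
  region_map(array(out, dims))
}
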