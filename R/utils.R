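# Low-level array helpers shared across modules. Arrays are 3D, 0-based
# lattice semantics with x fastest-varying (R's native column-major order).

# Shift an array by integer offset d: out[p] = a[p + d], `fill` outside.
shift_array <- function(a, d, fill = NA) {
  dm <- dim(a)
  out <- array(fill, dm)
  src <- dst <- vector("list", 3L)
  for (i in 1:3) {
    s <- seq_len(dm[i]) + d[i]
    keep <- s >= 1L & s <= dm[i]
    if (!any(keep)) return(out)
    dst[[i]] <- which(keep)
    src[[i]] <- s[keep]
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    a[src[[1]], src[[2]], src[[3]], drop = FALSE]
  out
}

# Central difference along `axis` with voxel size h; one-sided at the faces.
central_diff <- function(a, axis, h = 1) {
  dm <- dim(a)
  n <- dm[axis]
  up <- pmin(seq_len(n) + 1L, n)
  dn <- pmax(seq_len(n) - 1L, 1L)
  span <- (up - dn) * h
  idx <- function(ord) switch(axis,
    a[ord, , , drop = FALSE], a[, ord, , drop = FALSE], a[, , ord, drop = FALSE])
  num <- idx(up) - idx(dn)
  sw <- switch(axis, span, rep(span, each = dm[1]),
               rep(span, each = dm[1] * dm[2]))
  array(as.vector(num) / as.vector(sw), dm)
}

# --- FFT Gaussian smoothing -------------------------------------------------

.kfft_cache <- new.env(parent = emptyenv())

.gauss_kernel_fft <- function(pd, sigma) {
  key <- paste(c(pd, signif(sigma, 8)), collapse = "|")
  hit <- .kfft_cache[[key]]
  if (!is.null(hit)) return(hit)
  ax <- function(n, s) {
    if (s <= 1e-8) {
      k <- numeric(n); k[1] <- 1; return(k)
    }
    d <- pmin(0:(n - 1), n - (0:(n - 1)))
    k <- exp(-0.5 * (d / s)^2)
    k / sum(k)
  }
  k1 <- ax(pd[1], sigma[1]); k2 <- ax(pd[2], sigma[2]); k3 <- ax(pd[3], sigma[3])
  K <- outer(outer(k1, k2), k3)
  dim(K) <- pd
  Kf <- stats::fft(K)
  if (length(.kfft_cache) > 32L) rm(list = ls(.kfft_cache), envir = .kfft_cache)
  .kfft_cache[[key]] <- Kf
  Kf
}

# Gaussian smoothing with edge renormalization (and optional support weights):
# smooth(a*w)/smooth(w), computed on a zero-padded grid so there is no
# wrap-around. `sigma` in voxels per axis.
gaussian_smooth3 <- function(a, sigma, weights = NULL) {
  sigma <- rep(sigma, length.out = 3)
  if (all(sigma <= 1e-8)) return(a)
  dm <- dim(a)
  pad <- pmin(ceiling(3 * sigma) + 1, dm)  # kernel mass beyond one extent is negligible
  pd <- vapply(1:3, function(i) stats::nextn(dm[i] + 2 * pad[i], c(2, 3, 5)), 0)
  w <- if (is.null(weights)) array(1, dm) else weights
  ap <- array(0, pd); wp <- array(0, pd)
  ap[seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3])] <- a * w
  wp[seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3])] <- w
  Kf <- .gauss_kernel_fft(pd, sigma)
  sm <- function(x) Re(stats::fft(stats::fft(x) * Kf, inverse = TRUE)) / prod(pd)
  sa <- sm(ap)[seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3]), drop = FALSE]
  sw <- sm(wp)[seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3]), drop = FALSE]
  array(sa / pmax(sw, 1e-12), dm)
}

# --- Interpolation ----------------------------------------------------------

# Trilinear sampling of `a` at continuous 1-based coordinates (vectors).
# Coordinates are clamped to the lattice.
trilinear_sample <- function(a, x, y, z) {
  dm <- dim(a)
  x <- pmin(pmax(x, 1), dm[1]); y <- pmin(pmax(y, 1), dm[2]); z <- pmin(pmax(z, 1), dm[3])
  x0 <- pmin(floor(x), dm[1] - 1L); y0 <- pmin(floor(y), dm[2] - 1L)
  z0 <- pmin(floor(z), dm[3] - 1L)
  if (dm[1] == 1L) x0 <- rep(1, length(x))
  if (dm[2] == 1L) y0 <- rep(1, length(y))
  if (dm[3] == 1L) z0 <- rep(1, length(z))
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  sx <- 1L; sy <- dm[1]; sz <- dm[1] * dm[2]
  i000 <- (x0 - 1) * sx + (y0 - 1) * sy + (z0 - 1) * sz + 1
  x1 <- pmin(x0 + 1, dm[1]); y1 <- pmin(y0 + 1, dm[2]); z1 <- pmin(z0 + 1, dm[3])
  ix <- (x1 - x0) * sx; iy <- (y1 - y0) * sy; iz <- (z1 - z0) * sz
  v <- as.vector(a)
  v[i000]                * (1 - fx) * (1 - fy) * (1 - fz) +
  v[i000 + ix]           * fx       * (1 - fy) * (1 - fz) +
  v[i000 + iy]           * (1 - fx) * fy       * (1 - fz) +
  v[i000 + ix + iy]      * fx       * fy       * (1 - fz) +
  v[i000 + iz]           * (1 - fx) * (1 - fy) * fz +
  v[i000 + ix + iz]      * fx       * (1 - fy) * fz +
  v[i000 + iy + iz]      * (1 - fx) * fy       * fz +
  v[i000 + ix + iy + iz] * fx       * fy       * fz
}

nearest_sample <- function(a, x, y, z) {
  dm <- dim(a)
  x <- pmin(pmax(round(x), 1), dm[1])
  y <- pmin(pmax(round(y), 1), dm[2])
  z <- pmin(pmax(round(z), 1), dm[3])
  a[cbind(x, y, z)]
}

# 1-based voxel-center coordinate grids as vectors of length prod(dims).
coord_grids <- function(dm) {
  list(
    x = rep.int(seq_len(dm[1]), dm[2] * dm[3]),
    y = rep.int(rep(seq_len(dm[2]), each = dm[1]), dm[3]),
    z = rep(seq_len(dm[3]), each = dm[1] * dm[2])
  )
}

# --- Distance transform -----------------------------------------------------

# Euclidean distance (in mm) from every voxel to the nearest seed voxel.
distance_to_set <- function(seeds, spacing = c(1, 1, 1)) {
  dm <- dim(seeds)
  d2 <- edt_sq_cpp(as.logical(seeds), as.integer(dm), as.numeric(spacing))
  array(sqrt(d2), dm)
}

# --- Connected components ---------------------------------------------------

# Number of 6-connected foreground components (used for phantom QC).
connected_component_count <- function(mask) {
  dm <- dim(mask)
  lab <- array(0L, dm)
  idx <- which(mask != 0)
  if (length(idx) == 0L) return(0L)
  sx <- 1L; sy <- dm[1]; sz <- dm[1] * dm[2]
  g <- coord_grids(dm)
  ncomp <- 0L
  seen <- array(FALSE, dm)
  for (start in idx) {
    if (seen[start]) next
    ncomp <- ncomp + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      for (dstep in c(-sx, sx, -sy, sy, -sz, sz)) {
        nb <- cur + dstep
        ok <- nb >= 1L & nb <= length(seen)
        # reject wrap-around across x/y faces
        if (dstep == -sx) ok <- ok & g$x[cur] > 1L
        if (dstep ==  sx) ok <- ok & g$x[cur] < dm[1]
        if (dstep == -sy) ok <- ok & g$y[cur] > 1L
        if (dstep ==  sy) ok <- ok & g$y[cur] < dm[2]
        nb <- nb[ok]
        nb <- nb[mask[nb] != 0 & !seen[nb]]
        if (length(nb)) {
          seen[nb] <- TRUE
          queue <- c(queue, nb)
        }
      }
      queue <- unique(queue)
    }
  }
  ncomp
}
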