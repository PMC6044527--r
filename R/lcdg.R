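# First-order appearance model: linear combination of discrete Gaussians
# (LCDG) fitted to the empirical marginal gray-level distribution, then split
# into kidney/background submodels Pr(q | l).
#
# A discrete Gaussian over {0..Q-1} is defined by CDF differences at
# half-integer boundaries, renormalized to sum 1. The LCDG has exactly two
# positive dominant components (one per class) plus sign-alternate
# subordinate components that model the residual of the dominant mixture.

MIN_SIGMA <- 0.5

#' Discrete Gaussian probabilities over the gray-level set
#'
#' `P(q) proportional to pnorm(q + 0.5; mu, sigma) - pnorm(q - 0.5; mu, sigma)`,
#' renormalized over `{0..Q-1}`.
#'
#' @param mean,sd parameters in gray-level units (`sd > 0`).
#' @param q_levels number of gray levels Q.
#' @return numeric vector of length Q summing to 1.
#' @export
discrete_gaussian <- function(mean, sd, q_levels = 256L) {
  q <- 0:(q_levels - 1L)
  p <- stats::pnorm((q + 0.5 - mean) / sd) - stats::pnorm((q - 0.5 - mean) / sd)
  s <- sum(p)
  if (s < 1e-300) {  # numerically degenerate: unit spike at the nearest level
    p <- numeric(q_levels)
    p[min(max(round(mean), 0), q_levels - 1L) + 1L] <- 1
    return(p)
  }
  p / s
}

#' Empirical gray-level histogram of a volume
#'
#' @param v a [volume()].
#' @param mask optional [region_map()]; if given, only `mask == 1` voxels are
#'   counted.
#' @return object of class `gray_histogram`: relative frequencies over
#'   `{0..Q-1}` (sums to 1) with attribute `n` (voxel count).
#' @export
build_histogram <- function(v, mask = NULL) {
  stopifnot(inherits(v, "dwi_volume"))
  vals <- v$data
  if (!is.null(mask)) {
    stopifnot_same_lattice(v, mask, "volume and mask")
    vals <- vals[mask$labels == 1L]
    if (length(vals) == 0L) stop("empty mask: no voxels to histogram")
  }
  h <- tabulate(vals + 1L, nbins = v$q_levels)
  structure(h / sum(h), class = "gray_histogram", n = sum(h),
            q_levels = v$q_levels)
}

lcdg_mixture <- function(comp, q_levels) {
  # total signed mixture density of a component table
  dens <- numeric(q_levels)
  for (i in seq_len(nrow(comp)))
    dens <- dens + comp$weight[i] *
      discrete_gaussian(comp$mean[i], comp$sd[i], q_levels)
  dens
}

new_lcdg_model <- function(comp, q_levels, converged = TRUE) {
  structure(list(components = comp, q_levels = q_levels,
                 converged = converged),
            class = "lcdg_model")
}

#' @export
print.lcdg_model <- function(x, ...) {
  ns <- sum(x$components$role == "subordinate")
  cat(sprintf("<lcdg_model> 2 dominant + %d subordinate components over Q = %d\n",
              ns, x$q_levels))
  print(x$components, digits = 4)
  invisible(x)
}

#' Fit the two dominant discrete-Gaussian components
#'
#' EM fit of a 2-component discrete-Gaussian mixture to a histogram. The two
#' components are the positive dominant modes of the LCDG; the brighter mean
#' is assigned the kidney label when `kidney_brighter` (brightness ordering
#' flips with b-value and acquisition, hence the flag).
#'
#' @param h a `gray_histogram` from [build_histogram()].
#' @param kidney_brighter logical; kidney is the higher-mean class (default).
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @return An `lcdg_model` with 2 dominant components and no subordinates.
#' @export
fit_dominant <- function(h, kidney_brighter = TRUE, max_iter = 500, tol = 1e-9) {
  Q <- attr(h, "q_levels")
  q <- 0:(Q - 1L)
  occ <- which(h > 0)
  if (length(occ) < 2L)
    stop("degenerate histogram: need at least 2 distinct occupied gray levels")
  # moment/quantile initialization
  cw <- cumsum(h)
  qt <- function(p) q[which.min(abs(cw - p))]
  mu <- c(qt(0.25), qt(0.75))
  if (mu[1] == mu[2]) mu <- range(q[occ])
  sg <- rep(max(sqrt(sum(h * (q - sum(h * q))^2)) / 2, MIN_SIGMA), 2)
  w <- c(0.5, 0.5)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    P1 <- discrete_gaussian(mu[1], sg[1], Q)
    P2 <- discrete_gaussian(mu[2], sg[2], Q)
    mix <- w[1] * P1 + w[2] * P2
    mix <- pmax(mix, 1e-300)
    r1 <- w[1] * P1 / mix
    # weighted M-step over gray levels
    n1 <- sum(h * r1); n2 <- 1 - n1
    n1 <- max(n1, 1e-12); n2 <- max(n2, 1e-12)
    mu[1] <- sum(h * r1 * q) / n1
    mu[2] <- sum(h * (1 - r1) * q) / n2
    sg[1] <- max(sqrt(sum(h * r1 * (q - mu[1])^2) / n1), MIN_SIGMA)
    sg[2] <- max(sqrt(sum(h * (1 - r1) * (q - mu[2])^2) / n2), MIN_SIGMA)
    w <- c(n1, n2)
    ll <- sum(h * log(mix))
    if (is.finite(ll) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  ord <- order(mu)  # lower mean first
  mu <- mu[ord]; sg <- sg[ord]; w <- w[ord]
  cls <- if (kidney_brighter) c(0L, 1L) else c(1L, 0L)
  comp <- data.frame(weight = w, mean = mu, sd = sg,
                     role = "dominant", class = cls,
                     stringsAsFactors = FALSE)
  new_lcdg_model(comp, Q)
}

#' Fit the full LCDG (dominant + sign-alternate subordinates)
#'
#' Starting from the dominant 2-component fit, subordinate discrete
#' Gaussians are added greedily from the largest residual lobe (empirical
#' histogram minus current mixture), with the lobe's sign as the component's
#' weight sign. A candidate's weight is halved until the total mixture stays
#' non-negative, and the candidate is kept only if it improves the L1 fit by
#' at least `tol` -- so the L1 error is non-increasing in the number of
#' subordinates by construction. A final equality-constrained least-squares
#' re-fit of the subordinate weights (total weight pinned to 1) is kept when
#' it improves the fit and preserves non-negativity.
#'
#' @param h a `gray_histogram`.
#' @param max_subordinate maximum number of subordinate components.
#' @param tol minimum L1 improvement to accept a component.
#' @param kidney_brighter passed to [fit_dominant()].
#' @return An `lcdg_model`; `converged = FALSE` flags an early stop at the
#'   iteration cap.
#' @export
fit_lcdg <- function(h, max_subordinate = 8L, tol = 1e-4,
                     kidney_brighter = TRUE) {
  Q <- attr(h, "q_levels")
  model <- fit_dominant(h, kidney_brighter)
  comp <- model$components
  dens <- lcdg_mixture(comp, Q)
  l1 <- sum(abs(h - dens))
  for (k in seq_len(max_subordinate)) {
    resid <- as.numeric(h) - dens
    peak <- which.max(abs(resid))
    s <- sign(resid[peak])
    if (s == 0) break
    # contiguous lobe of matching sign around the peak
    same <- sign(resid) == s
    lo <- peak; while (lo > 1L && same[lo - 1L]) lo <- lo - 1L
    hi <- peak; while (hi < Q && same[hi + 1L]) hi <- hi + 1L
    idx <- lo:hi
    wgt <- abs(resid[idx])
    mass <- sum(wgt)
    if (mass < tol) break
    qv <- idx - 1
    mu <- sum(wgt * qv) / mass
    sg <- sqrt(sum(wgt * (qv - mu)^2) / mass)
    sg <- min(max(sg, MIN_SIGMA), Q / 4)
    wnew <- s * mass
    psi <- discrete_gaussian(mu, sg, Q)
    accepted <- FALSE
    for (halve in 1:20) {
      cand <- rbind(comp, data.frame(weight = wnew, mean = mu, sd = sg,
                                     role = "subordinate", class = NA_integer_,
                                     stringsAsFactors = FALSE))
      # keep total weight at 1 by rescaling the dominant pair
      cand <- rebalance_weights(cand)
      cdens <- lcdg_mixture(cand, Q)
      if (min(cdens) >= -1e-12) {
        cl1 <- sum(abs(h - cdens))
        if (l1 - cl1 >= tol) {
          comp <- cand; dens <- cdens; l1 <- cl1; accepted <- TRUE
        }
        break
      }
      wnew <- wnew / 2
      if (abs(wnew) < 1e-8) break
    }
    if (!accepted) break
  }
  # least-squares refinement of subordinate weights (sum of all weights = 1)
  subs <- which(comp$role == "subordinate")
  if (length(subs) > 0L) {
    refined <- refine_weights(h, comp, Q)
    rdens <- lcdg_mixture(refined, Q)
    if (min(rdens) >= -1e-12 && sum(abs(h - rdens)) <= l1) {
      comp <- refined; dens <- rdens; l1 <- sum(abs(h - rdens))
    }
  }
  m <- new_lcdg_model(comp, Q)
  m$l1_error <- l1
  m
}

rebalance_weights <- function(comp) {
  dom <- comp$role == "dominant"
  target <- 1 - sum(comp$weight[!dom])
  cur <- sum(comp$weight[dom])
  if (cur > 1e-12 && target > 1e-12)
    comp$weight[dom] <- comp$weight[dom] * target / cur
  comp
}

refine_weights <- function(h, comp, Q) {
  # minimize ||h - Psi w||_2 subject to sum(w) = 1, dominant shape fixed;
  # solved by the KKT system of the equality-constrained least squares.
  Psi <- vapply(seq_len(nrow(comp)),
                function(i) discrete_gaussian(comp$mean[i], comp$sd[i], Q),
                numeric(Q))
  A <- crossprod(Psi)
  b <- crossprod(Psi, as.numeric(h))
  k <- nrow(comp)
  K <- rbind(cbind(A, rep(1, k)), c(rep(1, k), 0))
  rhs <- c(b, 1)
  sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
  if (is.null(sol)) return(comp)
  w <- sol[seq_len(k)]
  if (any(w[comp$role == "dominant"] <= 0)) return(comp)
  comp$weight <- w
  comp
}

#' Split a fitted LCDG into per-class submodels
#'
#' Each subordinate component is assigned to the dominant class whose
#' submodel it improves, greedily minimizing the overlap between the two
#' weighted class submodels. Each submodel is clipped to non-negative values
#' and renormalized to a proper distribution `Pr(q | l)`. The separating
#' threshold `t*` is the gray level between the two dominant means where the
#' weighted submodels cross; if no crossing exists, the midpoint of the
#' dominant means is used and flagged.
#'
#' @param model an `lcdg_model` from [fit_lcdg()] (or [fit_dominant()]).
#' @return An `lcdg_submodels` object: list with `p0`, `p1` (length-Q
#'   distributions), `priors` (class weights), `threshold`, and
#'   `threshold_fallback` flag.
#' @export
split_classes <- function(model) {
  stopifnot(inherits(model, "lcdg_model"))
  comp <- model$components
  Q <- model$q_levels
  dom <- which(comp$role == "dominant")
  subs <- which(comp$role == "subordinate")
  cls <- comp$class
  # greedy assignment, largest |weight| first
  for (i in subs[order(-abs(comp$weight[subs]))]) {
    best <- NA; best_ov <- Inf
    for (l in c(0L, 1L)) {
      cls[i] <- l
      s0 <- class_density(comp, cls, 0L, Q)
      s1 <- class_density(comp, cls, 1L, Q)
      ov <- sum(pmin(pmax(s0, 0), pmax(s1, 0)))
      if (ov < best_ov) { best_ov <- ov; best <- l }
    }
    cls[i] <- best
  }
  # clip to non-negative; a vanishing floor keeps every gray level in the
  # support so that a zero-prior class can never win by default on ties
  s0 <- pmax(class_density(comp, cls, 0L, Q), 0) + 1e-12
  s1 <- pmax(class_density(comp, cls, 1L, Q), 0) + 1e-12
  w0 <- sum(comp$weight[cls == 0L & !is.na(cls)])
  w1 <- sum(comp$weight[cls == 1L & !is.na(cls)])
  p0 <- s0 / sum(s0)
  p1 <- s1 / sum(s1)
  # crossing of the weighted submodels between the dominant means
  mu <- comp$mean[dom]
  mcls <- comp$class[dom]
  lo <- min(mu); hi <- max(mu)
  lo_cls <- mcls[which.min(mu)]
  qs <- seq.int(ceiling(lo), floor(hi))
  thr <- NA_integer_; fallback <- FALSE
  if (length(qs) > 0) {
    wl <- if (lo_cls == 0L) w0 * p0 else w1 * p1
    wh <- if (lo_cls == 0L) w1 * p1 else w0 * p0
    d <- wh[qs + 1L] - wl[qs + 1L]  # negative near lo, positive near hi
    cross <- which(d >= 0)
    if (length(cross) > 0 && cross[1] > 1) {
      thr <- qs[cross[1]]
    }
  }
  if (is.na(thr)) {
    thr <- as.integer(round(mean(mu)))
    fallback <- TRUE
    warning("no crossing between class submodels; threshold set to midpoint ",
            thr)
  }
  structure(list(p0 = p0, p1 = p1, priors = c(`0` = w0, `1` = w1),
                 threshold = thr, threshold_fallback = fallback,
                 q_levels = Q),
            class = "lcdg_submodels")
}

class_density <- function(comp, cls, l, Q) {
  idx <- which(cls == l & !is.na(cls))
  dens <- numeric(Q)
  for (i in idx)
    dens <- dens + comp$weight[i] *
      discrete_gaussian(comp$mean[i], comp$sd[i], Q)
  dens
}

#' Class-conditional intensity likelihood Pr(q | l)
#'
#' @param submodels an `lcdg_submodels` from [split_classes()].
#' @param q gray level(s) in `{0..Q-1}` (vectorized).
#' @param l label, 0 (background) or 1 (kidney).
#' @return probabilities `Pr(q | l) >= 0`.
#' @export
class_likelihood <- function(submodels, q, l) {
  stopifnot(inherits(submodels, "lcdg_submodels"))
  if (any(q < 0 | q > submodels$q_levels - 1L))
    stop("gray level out of range")
  p <- if (l == 1L) submodels$p1 else submodels$p0
  p[q + 1L]
}
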