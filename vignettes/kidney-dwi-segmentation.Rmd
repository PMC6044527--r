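---
title: "Appearance- and shape-guided level-set segmentation of kidneys in DW-MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Appearance- and shape-guided level-set segmentation of kidneys in DW-MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kidneyseg)
```

## The problem and the model

Diffusion-weighted MRI acquires, for each diffusion weighting $b$
(s/mm$^2$), a 3D gray-level volume $\mathbf{g}$ on a lattice
$\mathbf{R}$ with values in $\mathbf{Q} = \{0, \dots, Q-1\}$. The kidney
must be separated from the surrounding abdomen in *every* $b$-scan, but
both SNR and kidney/background contrast decay roughly as
$S_b = S_0 e^{-b \cdot \mathrm{ADC}}$, so a single appearance cue is not
enough at high $b$. The package models an image and its binary region map
$\mathbf{m}$ ($1$ = kidney) jointly as
$P(\mathbf{g},\mathbf{m}) = P(\mathbf{g}\,|\,\mathbf{m})\,
P_{\mathrm{sp}}(\mathbf{m})\, P_\mathbf{V}(\mathbf{m})$:

1. **First-order appearance** $P(\mathbf{g}|\mathbf{m})$: the empirical
   marginal over gray levels is approximated by a linear combination of
   discrete Gaussians (LCDG) — exactly two positive *dominant* components,
   one per class, plus sign-alternate *subordinate* components — and then
   split into class-conditional submodels $\Pr(q\,|\,l)$. A discrete
   Gaussian here is the vector of CDF differences at half-integer
   boundaries, renormalized over $\mathbf{Q}$.
2. **Fourth-order spatial interactions** $P_\mathbf{V}(\mathbf{m})$: a
   Markov–Gibbs random field over 35 translation-invariant clique families
   of the 26-neighborhood — 13 pair directions, 13 collinear triples, and
   9 planar $2{\times}2$ quadruples (3 axis-aligned, 6 diagonal-plane).
   The Gibbs potentials are estimated *analytically* from the
   label-equality frequencies of the current map:
   $V_{2:\mathrm{eq}} = 4(F_\mathrm{eq}-\tfrac12) = -V_{2:\mathrm{ne}}$,
   $V_{3:\mathrm{eq3}} = \tfrac{16}{3}(F_\mathrm{eq3}-\tfrac14)
   = -V_{3:\mathrm{eq2}}$, and for quadruples
   $\mathbf{V}_4 = \lambda^{*} (f_4, f_3, f_2)$ with
   $f_4 = F_\mathrm{eq4}-\tfrac18$, $f_3 = F_\mathrm{eq3}-\tfrac12$,
   $f_2 = F_\mathrm{eq2}-\tfrac38$ and
   $\lambda^{*} = \sum_a (f_4^2+f_3^2+f_2^2) \big/
   \sum_a (\tfrac{7}{64} f_4^2 + \tfrac14 f_3^2 + \tfrac{15}{64} f_2^2)$.
   The offsets are the equiprobable-label baselines (for four binary
   labels: all-equal $2/16$, exactly-three-equal $8/16$, two-and-two
   $6/16$), and the $\lambda^{*}$ weights are the corresponding
   $p(1-p)$ variances, which is what makes the printed coefficients
   internally consistent. The *quadruple "eq2" class is the two-and-two
   split*; this is the only reading under which the baselines and weights
   agree. From these potentials the package computes voxel-wise
   *conditional* probabilities
   $\Pr_{\mathbf{V}:\mathbf{p}}(l) \propto \exp E_\mathbf{p}(l)$, where
   $E_\mathbf{p}(l)$ sums the potentials of all cliques containing
   $\mathbf{p}$ with its label replaced by $l$. The joint Gibbs
   normalizer $Z_\mathbf{V}$ is never computed — only voxel-wise
   probabilities enter the guidance — and cliques leaving the lattice are
   skipped rather than padded, so frequencies stay unbiased.
3. **Adaptive shape prior** $P_{\mathrm{sp}}(\mathbf{m})$: baseline
   ($b=0$) training scans and their kidney maps are co-aligned to a
   reference subject (chosen per test subject by maximal normalized
   cross-correlation after centroid alignment) with a nonrigid
   SSD-minimizing registration. For each test voxel, the co-aligning
   deformation field gives a database location; a window search collects
   all training voxels within an intensity tolerance of the test voxel's
   gray level, growing the window by 2 per axis until a match exists, and
   $\Pr_{\mathrm{sp}:\mathbf{p}}(1)$ is the kidney fraction among the
   matches. The intensity matching is what makes the prior *adaptive*:
   residual misalignment is compensated by searching, not by trusting the
   mapped location.

The three probabilities combine voxel-wise into
$\Omega_{\mathrm{kd}} = \Pr(q|1)\Pr_{\mathbf{V}}(1)\Pr_{\mathrm{sp}}(1)$
and
$\Omega_{\mathrm{bg}} = \Pr(q|0)\,(1-\Pr_{\mathbf{V}}(1))\,(1-\Pr_{\mathrm{sp}}(1))$
(the background term is the symmetric three-factor product), normalized to
$\Pr_\mathbf{p}(1)$, and drive a geometric level set
$\Phi_{n+1} = \Phi_n - \tau F_n |\nabla \Phi_n|$ with
$F_n(\mathbf{p}) = \kappa\,\vartheta_\mathbf{p}$, where
$\vartheta_\mathbf{p} = -\Pr_\mathbf{p}(1)$ if $\Pr_\mathbf{p}(1) > 0.5$
and $+\Pr_\mathbf{p}(0)$ otherwise (ties take the background branch, per
the strict inequality). $\Phi$ is a signed distance map, *positive
inside*. Per scan the pipeline is: fit the LCDG; apply the adapted prior;
form the Bayes initial map
$m_{\mathrm{ini}}(\mathbf{p}) = 1 \iff \Pr(g_\mathbf{p}|1)
\Pr_{\mathrm{sp}}(1) > \Pr(g_\mathbf{p}|0)\Pr_{\mathrm{sp}}(0)$; estimate
the Gibbs potentials from $m_{\mathrm{ini}}$; build the speed; evolve from
$m_{\mathrm{ini}}$'s signed distance. All $b$-scans share one prior
(adapted from the test subject's $b=0$ scan) but get their own appearance
and spatial models.

## Numerical and design choices

**Curvature sign and the speed product.** With the positive-inside
convention, the package defines $\kappa$ as the divergence of the
*outward* normal, $-\nabla\Phi/|\nabla\Phi|$: a convex boundary has
$\kappa > 0$, a sphere of radius $r$ has $\kappa \approx 2/r$, a plane
$0$, and negating $\Phi$ flips the sign (`mean_curvature()`). In the speed
product the curvature enters by *magnitude*, $F = |\kappa|\,\vartheta$:
$\vartheta$ alone decides the direction of motion and the curvature
modulates the rate, so rough surface patches move fastest and flat
interfaces that already separate the two posterior regions are stationary.
Using the signed curvature in the product instead makes the front
anti-diffusive wherever the boundary is concave — a dent such as the
renal hilum erodes in a runaway front, which contradicts both the
intended smoothing role of $\kappa$ and the uniform-pull behavior (a
sphere under constant kidney pull must expand). This is the package's own
resolution of an ambiguity in the speed definition; everything else about
the case split is literal.

**Level-set numerics.** Godunov upwind gradients; CFL time step
$\tau \le 0.45\,\min(\text{spacing})/\max|F_n|$ recomputed per iteration
when `tau = NULL`; exact Euclidean redistancing (Felzenszwalb distance
transform, spacing-aware) every 20 iterations; a narrow band of 6 voxels;
convergence when the zero-level mask changes by less than 0.1% of its
volume over 10 consecutive iterations, capped at 200 iterations. The
evolution loop and distance transform are C++ (Rcpp); single-voxel
remnants whose central-difference gradient vanishes freeze rather than
disappear, which the divergence guard (mask empties or floods) treats as
benign.

**LCDG fitting.** The dominant pair is fitted by EM on the binned
histogram with a $\sigma \ge 0.5$ floor (a pure spike then concentrates
$\approx$ 99.7% of its mass within $\pm 1$ level). Subordinates are added
greedily from the largest contiguous residual lobe, signed by the
residual; a candidate's weight is halved until the total mixture is
non-negative and the candidate is kept only if it improves the $L_1$ fit
by at least `tol` — monotone improvement is therefore guaranteed by
construction, not hoped for. A final equality-constrained least squares
re-fit of the weights (total pinned to 1) is kept only under the same two
guards. Submodels are clipped to non-negative, floored at $10^{-12}$ (so
a class with a hard-zero prior can never win a tie by default), and
renormalized; the threshold $t^{*}$ is the crossing of the weighted
submodels between the dominant means, falling back to their midpoint with
a warning. Which class is "kidney" is a config flag
(`lcdg$kidney_brighter`, default TRUE) because brightness ordering flips
with $b$ and acquisition.

**Bias correction and equalization.** The cited non-parametric
inhomogeneity correction is realized as a log-domain iterative low-pass
estimator: the low-frequency component of the log-intensity residual
(Gaussian kernel of physical scale `bias_smoothness_mm`, default 40 mm,
mask-normalized so zero-intensity voxels carry no weight) is accumulated
into the field, which is normalized to mean 1. Because the field is
low-frequency by assumption it is estimated on a 2× coarser grid and
upsampled. Histogram equalization uses the midpoint-CDF convention
(uniform input maps to identity up to one level) and runs *after* bias
correction; the order is a package decision — the two operations nearly
commute at these scales, and correcting first prevents the equalization
from stretching the inhomogeneity.

**Registration.** The shape database and test co-alignment use a
multi-resolution (3-level) demons-style registration minimizing voxel-wise
SSD with Gaussian field regularization (`sigma_field_mm`, default 3 mm;
iterations 60/40/25 coarse-to-fine). The returned field lives on the
fixed lattice and maps into the moving lattice; maps are warped
nearest-neighbor so they stay binary. The best field seen — with the
identity as initial candidate — is returned after full-resolution SSD
evaluation, so the SSD contracts (never worse than no registration,
non-increasing across levels) hold by construction. The backend is
deliberately behind `register_nonrigid()` so it can be swapped.

**Shape-prior defaults.** Window $3^3$ growing to $11^3$, intensity
tolerance 10 gray levels (of 256). If the largest window still has no
intensity match, label occurrences in that window are used ignoring
intensity — the search then degrades gracefully into a plain local atlas
vote. The deformation field used for mapping is the test-to-reference
field; mapped coordinates are rounded to the nearest voxel.

## What the phantom emulates — and what it does not

`phantom_spec()` encodes the study conditions: 1.28 × 1.28 mm in-plane
resolution with 4 mm sections; twelve b-values 0–1000 s/mm$^2$;
mono-exponential per-tissue decay (cortex ADC 2.0×10⁻³, medulla
1.8×10⁻³ mm²/s); Rician noise (magnitude MR data; σ = 8 gray levels, so
SNR at $b=1000$ is under a third of baseline); a smooth multiplicative
bias field (20% peak); and per-subject anatomy — a bean-shaped kidney
(ellipsoid with a hilum notch, cortex shell over medulla) under random
smooth deformations (5 mm RMS), translations and scale changes. The
background is a three-tissue blob layout shared across the cohort (real
abdomens agree across subjects up to deformation) with 30%
subject-specific variance, plus a liver/spleen-like organ abutting the
kidney at near-kidney intensity (S0 160 vs cortex 170) — the low-contrast
boundary that makes pure appearance models fail. All randomness derives
from one seed.

The phantom does *not* simulate k-space acquisition, motion between
b-values, eddy-current distortion, partial-volume blur, or multi-organ
contact on all sides. Passing the phantom suite therefore demonstrates
the estimators' correctness (they are additionally checked against
brute-force oracles at small sizes) and the pipeline's robustness to
noise, bias, low contrast and inter-subject deformation — not clinical
performance on patient data.

Problem sizes in the test suite and `scripts/acceptance.R` were chosen as
the smallest at which the cohort statistics stabilize: 8 subjects at
$48^3$ voxels with $b \in \{0, 500, 1000\}$ for the leave-one-subject-out
runs, $64^3$ maps for the estimator-neutrality checks, $10^6$ samples for
LCDG recovery, and exhaustive enumeration at $4^3$–$6^3$ for the oracle
equivalences.

## Known limitations

- Binary labels only; no multi-organ or cortex/medulla output, although
  the phantom provides compartment masks.
- The conditional reading of $\Pr_{\mathbf{V}:\mathbf{p}}$ (vs. a joint
  MAP under $P_\mathbf{V}$) is a modelling decision; graph-cut MAP
  inference is out of scope.
- The demons backend assumes comparable intensity profiles between
  subjects (it minimizes raw SSD after preprocessing); cross-protocol
  registration would need a different similarity.
- With a flat guidance field ($|\kappa| \approx 0$ everywhere relevant or
  $\vartheta$ uniformly zero) the front does not move; the Bayes initial
  map, not the evolution, carries such cases.
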