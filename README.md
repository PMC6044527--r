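# kidneyseg

3D kidney segmentation from diffusion-weighted MRI (DW-MRI) in R.

Segmenting the kidney from its surrounding abdominal structures in DW-MRI is
the gateway step for any downstream diffusion analysis (ADC mapping,
transplant-status assessment), and it is hard for exactly the reasons DW-MRI
is valuable: signal-to-noise ratio and kidney/background contrast collapse
as the diffusion weighting (b-value) grows, and breathing, heartbeat and
inter-patient anatomy move and reshape the organ. `kidneyseg` implements a
fully automatic geometric (level-set) deformable boundary whose evolution is
guided by a joint Markov–Gibbs random field (MGRF) model with three
components, each estimated from the data being segmented:

- **First-order appearance**: the marginal gray-level distribution is
  approximated by a *linear combination of discrete Gaussians* (LCDG) — two
  positive dominant components (kidney, background) plus sign-alternate
  subordinate components — and split into class-conditional submodels
  Pr(q | l).
- **Fourth-order spatial interactions**: pair, collinear-triple and planar
  2×2 quadruple clique families on the 26-neighborhood, with Gibbs
  potentials estimated *analytically* from label-equality frequencies:
  V₂:eq = 4(F_eq − ½), V₃:eq3 = (16/3)(F_eq3 − ¼), and quadruple potentials
  λ\*·(F_eq4 − ⅛, F_eq3 − ½, F_eq2 − ⅜). These give voxel-wise conditional
  label probabilities Pr_V:p(l).
- **Adaptive shape prior**: training kidney maps are co-aligned by nonrigid
  SSD-minimizing registration into a shape database; for each test voxel an
  intensity-matched window search around its mapped database location
  yields Pr_sp:p(l) as the label's relative occurrence among matches.

The three are combined voxel-wise, Ω_kd = Pr(q|1)·Pr_V(1)·Pr_sp(1) and
Ω_bg = Pr(q|0)·(1−Pr_V(1))·(1−Pr_sp(1)), into the probability
Pr_p(1) = Ω_kd/(Ω_kd+Ω_bg) that drives the level-set speed F = κ·ϑ_p, with
ϑ_p = −Pr_p(1) where Pr_p(1) > ½ and +Pr_p(0) otherwise and κ the mean
boundary curvature. Each b-value scan is segmented separately with its own
appearance and spatial models; the shape prior, built from baseline (b = 0)
scans, is shared.

The package also ships preprocessing (non-parametric bias-field correction
and histogram equalization), evaluation metrics (Dice similarity
coefficient, 95-percentile modified Hausdorff distance in mm, percentage
kidney volume difference), volume I/O (NIfTI-1, Analyze 7.5, raw+JSON), and
a synthetic multi-subject, multi-b-value phantom generator so the entire
method can be exercised and validated without clinical data.

## Worked example

Simulate an 8-subject phantom cohort and segment one subject
leave-one-subject-out:

```r
library(kidneyseg)

spec   <- phantom_spec(dims = c(48L, 48L, 48L), b_values = c(0, 500, 1000),
                       n_subjects = 8L, seed = 1L)
cohort <- generate_cohort(spec)

fold <- run_loo_fold(cohort, test_index = 1L)
fold$evaluation
#>      b       dsc    mhd95     pkvd
#> 1    0 0.9854523 1.810193 2.922478
#> 2  500 0.9897068 1.280000 2.050170
#> 3 1000 0.9894377 1.280000 2.035385
```

Each row evaluates the final mask of one b-value scan against the phantom's
ground truth: `dsc` is the Dice overlap (1 = perfect), `mhd95` the 95th
percentile of symmetric boundary-to-boundary distances in mm, and `pkvd`
the kidney volume error as a percentage of the true volume. Accuracy holds
up at b = 1000 — the lowest-SNR, lowest-contrast scan — because the shape
prior adapted from the b = 0 scan and the spatial model compensate for the
weak appearance cue.

The same pipeline is scriptable from a shell through the thin launcher in
`inst/cli/` (`simulate`, `preprocess`, `fit-appearance`, `build-shape-db`,
`adapt-prior`, `segment`, `evaluate`).

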