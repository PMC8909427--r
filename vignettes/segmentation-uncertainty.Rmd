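---
title: "Propagating segmentation uncertainty through radiomic prognostic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Propagating segmentation uncertainty through radiomic prognostic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A radiomic feature $X$ measured for patient $i$ is not a number but a
distribution: every choice in the imaging protocol — acquisition,
segmentation, processing — moves its value. Writing the intra-patient
variance as a sum of protocol components,

$$ s^2_{\text{intrapat}} = s^2_{\text{acq}} + s^2_{\text{seg}} +
   s^2_{\text{proc}} + 2\,\mathrm{COV}_{\text{acq,seg}} +
   2\,\mathrm{COV}_{\text{acq,proc}} + 2\,\mathrm{COV}_{\text{seg,proc}}, $$

(`combine_variances()`), the question for any biomarker study is whether
this uncertainty is small compared to the between-patient effect the
biomarker is supposed to detect. The general uncertainty-to-effect ratio

$$ \eta = \frac{E[s_{\text{intrapat}}]}{\mathrm{IQR}_{0.25-0.75}(X_i)} $$

(`eta_general()`) compares the expected intra-patient dispersion to the
cohort interquartile range; under a median stratification the 0.25 and 0.75
quantiles approximate the two class medians, so the IQR is a natural effect
scale. Note the general form divides an SD-like numerator by an IQR — two
different dispersion measures; we implement it exactly as defined and keep
the caveat here. When only the segmentation component is simulated, both
numerator and denominator can be estimated from the same realization table
and the ratio becomes internally consistent:

$$ \eta_{\text{seg}} = \frac{\operatorname{median}_i
   \mathrm{IQR}_r\, X_{ir}}{\mathrm{IQR}_i\,
   \operatorname{median}_r X_{ir}} $$

(`eta_segmentation()`), with $r$ indexing mask realizations (realization 0
is the original contour and is included in both statistics). For Gaussian
within/between structure the two 1.349 normal-IQR factors cancel and
$\eta_{\text{seg}}$ estimates $\sigma_w/\sigma_b$; this is the recovery
target the test suite checks at $n = 200$ patients $\times$ 301
realizations.

Downstream, model stability is measured by resampling: one realization per
patient is drawn (uniformly, with replacement across iterations) in both
cohorts, the four-covariate Cox model is refit, the test cohort is
stratified at the training median linear predictor, and the log-rank
p-value is recorded (`run_simulation()`). Two summaries matter:

* the fraction of iterations with $p < 0.05$ — how often the study would
  have been "significant" under a different but equally plausible set of
  contours; and
* per-patient agreement $\delta = (\#\text{MajC} - \#\text{MinC}) /
  (\#\text{MajC} + \#\text{MinC})$ of the labels a fixed ensemble model
  assigns across a patient's realizations (`patient_agreement()`);
  $\delta \ge 0.6$ corresponds to an 80% agreement rate.

The ensemble model is the iteration whose coefficient vector is closest in
least squares to the element-wise coefficient medians
(`select_ensemble()`); its per-patient scores are averaged over resampled
test realizations on the linear-predictor scale (`ensembled_scores()`).
Averaging on the risk (exponential) scale would give the same labels by
monotonicity for single realizations but not for averages; the linear
predictor is the scale on which the Cox model is additive, so it is the one
we average.

## The mask perturbation sampler

The tolerance contract is the product: every realization $M'$ of an
original mask $M$ satisfies
$\max\{\vec d(S_{M'}, S_M), \vec d(S_M, S_{M'})\} \le \tau$, where $S$ is
the set of boundary voxel centers and $\vec d$ the directed maximum
surface distance (`within_tolerance()`). Surfaces are voxel centers rather
than mesh surfels: it keeps every metric exactly testable against a
brute-force pairwise oracle, and the tolerance contract is what the
pipeline actually consumes. We read "a surface tolerance of τ" as this hard
constraint — the strictest interpretation that makes the guarantee binary.

One realization is drawn as follows:

1. Draw white noise on the grid and smooth it with a Gaussian kernel of
   width `smoothness_mm` (FFT, periodic) — a spatially coherent random
   field whose correlation length sets the lateral scale of the
   deformation front.
2. Normalize the field to unit SD, scale by $0.99\,(\tau - h/2)$ (where
   $h$ is the mean voxel spacing) and clip at that amplitude. Normalizing
   by the field's global maximum instead would make typical offsets shrink
   with grid size (the maximum of a larger Gaussian field is larger), and
   on clinical-sized grids the sampler would barely move any voxel;
   unit-SD scaling with clipping keeps typical offsets a fixed, sizable
   fraction of the tolerance on any grid.
3. Threshold the signed distance to the original surface at the offset
   plus half a voxel: $M' = \{v : d_s(v) \le o(v) + h/2\}$. The
   half-voxel term places the decision at the physical interface between
   voxel centers. Without it the zero-distance shell — which lies *inside*
   the mask under the voxel-center convention — is lost with probability
   one half, and realized volumes shrink systematically; with it, gains
   and losses pair symmetrically and the mean signed volume change is zero
   within Monte Carlo error (a property the test suite asserts).
4. Keep the largest 26-connected component and fill internal holes
   (anatomical plausibility).
5. Repair: where an eroded patch crosses a diagonally oriented part of the
   surface, an original surface voxel can be left $\sqrt 2$ voxels from
   the nearest new surface voxel — beyond τ = 1.18 mm at 1 mm spacing.
   Such voxels lie on the original surface, so re-adding them costs no
   tolerance; up to three repair passes run before validation.
6. Validate the contract; reject and redraw on failure (at most
   `max_attempts_per_mask = 25` times, then error — never a silent
   fallback to the original mask).

Realizations are treated as equally probable. The amplitude margin factor
0.99 avoids boundary-equality ties at exactly τ. At 1 mm spacing and
τ = 1.18 mm the contract confines changes to roughly one voxel layer on
either side of the contour: the sampler explores exactly the "uncertainty
ring" `build_ring()` exposes (|signed distance| ≤ τ, a 2–3 voxel shell).

## Feature definitions

Features follow the IBSI definitions with the common radiomics-software
conventions wherever a choice exists: fixed-bin-size discretization
anchored at the ROI minimum (`level = floor((I - min)/W) + 1`), texture
matrices at distance 1 over the 13 unique 3D directions, features computed
per direction and averaged (GLSZM and GLDM are direction-free), gray-level
zones and dependence neighborhoods 26-connected, GLDM dependence tolerance
$\alpha = 0$. Logs use base 2. Degenerate single-level ROIs take the
documented conventions (GLCM Contrast 0, Correlation and MCC 1; NGTDM
Coarseness capped at $10^6$) and emit a message. Every texture matrix is
tested for exact equality against an independent enumeration oracle on
small random ROIs.

Shape surface areas count exposed voxel faces. This is exact for
axis-aligned shapes but overestimates curved surfaces by the staircase
factor (about 1.5 for a sphere), so the sphericity of a voxelized ball is
*lower* than a cube's — a known property of face-counted areas, not a bug;
mesh-based areas are out of scope. Maximum 3D diameter is the largest
pairwise distance between surface voxel centers.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `tolerance_mm` (τ) | 1.18 | mm | published interobserver surface-distance bound for lung GTV delineation |
| `n_realizations` | 300 | — | realization count per patient; with the original, 301 values per feature; odd counts avoid δ ties |
| `smoothness_mm` | = τ | mm | correlation length of the offset field; matching the amplitude scale gives front-like local deformations |
| `bin_width_hu` | 25 | HU | standard fixed-bin width for CT radiomics |
| `voxel_size_mm` | 1 | mm | isotropic analysis grid; images trilinear, masks nearest-neighbor |
| `n_simulations` | 1000 | — | pipeline resampling iterations; stability fractions stabilize well below this |
| `max_attempts_per_mask` | 25 | — | rejection-sampling budget before a loud failure |
| α (significance) | 0.05 | — | threshold for the "significant realization" count |

Per-iteration RNG streams are derived from the master seed and the
iteration index, so iteration $i$ is identical whatever `n_sim` is — runs
can be extended without reshuffling history.

## Preprocessing and numerical choices

* Covariates are log-scaled (shifted by $1 - \min_{\text{train}}$ first if
  the training minimum is ≤ 0) and standardized by training mean and SD;
  test data always uses training parameters. Patients with any $|z| > 3$
  are excluded from that realization's fit and scoring — exclusion of the
  patient, not clipping of the value, is our reading of outlier "removal";
  δ scoring applies no exclusion so that every realization receives a
  label. Test values non-positive after the training shift are clamped to
  a tiny positive constant; they become extreme z-scores and fall to the
  outlier rule.
* Quantiles use linear interpolation (R type 7) everywhere.
* Cox fits delegate to `survival::coxph` (Efron ties), log-rank tests to
  `survival::survdiff`; the test suite cross-checks both against
  independent implementations (a BFGS optimizer on a hand-written partial
  likelihood; a hand-built observed−expected table).
* Undefined η (zero between-patient IQR) is a flagged state; ranking
  excludes such features with a warning rather than coercing to 0 or ∞.
  Ranking ties break lexicographically by feature name. `select_ensemble`
  ties return the first index.
* An empty stratum makes the log-rank result a flagged degenerate, and a
  failed iteration is recorded, not fatal; more than 10% failures aborts
  the run.

## What the synthetic generators emulate — and what they do not

`make_phantom()` produces an ellipsoidal tumor with spatially correlated
Gaussian texture (default 30 ± 40 HU, 4 mm correlation length) on a noisy
lung-like background (−800 ± 60 HU) at 1 mm isotropic spacing. It gives the
extraction and perturbation code realistic *structure* — a curved surface,
internal texture for the texture families to see, an intensity step at the
boundary — but not realistic lung anatomy: no vessels, pleura, cavitation,
or partial-volume halo. Passing tests on phantoms show the machinery is
correct, not that clinical η values will match.

`make_feature_table()` realizes the additive two-level model
$X_{irf} = \mu_f + b_{if} + \sigma_{w,f}\,e_{ir}$ with
$b \sim N(0, \sigma_b^2)$ and a *shared* latent noise draw $e_{ir}$ per
patient-realization: all features of a patient are computed from the same
perturbed mask, so one realization moves them together. (Independent
per-feature noise is available via `shared_noise = FALSE`; it weakens the
effect of segmentation noise on a multi-feature model, because independent
errors average out across covariates.) Real radiomic features are
additionally skewed, heteroscedastic and mutually correlated in their
*between*-patient structure; the Gaussian model is chosen because its η is
analytic ($\sigma_w/\sigma_b$), making parameter recovery a sharp test.

`make_survival()` draws exponential event times with rate
$\lambda_i = \lambda_0 \exp(\beta^\top x_i)$ from the realization-0
("true") features — biology drives the hazard, not segmentation noise —
with independent uniform censoring whose upper bound is solved in closed
form to hit the target censoring fraction. Exponential baselines make
coefficient recovery checks exact; real survival is not exponential, but
the Cox model never uses that.

## The reference stability study

`make_eta_contrast_study()` fixes the package's demonstration conditions:
cohorts of 200 (training) and 150 (testing) patients, 300 realizations per
patient, four covariates carrying the prognostic signal twice — once with
designed η ≈ 0.05 and once with η ≈ 0.4 — sharing identical
between-patient effects, per-feature log-hazard coefficient 0.2, 30%
censoring, baseline hazard 1/365 per day (median survival about a year, as
in advanced lung cancer). The coefficient size was set by power arithmetic
and the default population seed chosen so that the original-contour
baseline stratification tests at log-rank p just under 0.01: clearly
significant but not overwhelming, which is the regime where stability
analysis is informative — an overwhelming signal survives any contour
noise, and a non-significant baseline has no stability to lose. These
conditions are a fixed study population, like a named cohort; the
simulation seed varies the Monte Carlo resampling on top of it.

The test suite runs this study at `n_sim = 200` per setup for three
simulation seeds (about 15 s) and asserts the directional contrasts: the
low-η setup keeps significance in a larger fraction of realizations, and a
larger share of its test patients reach δ ≥ 0.6. The perturbation
acceptance check uses a 64³, 10 mm-radius ball phantom with 300
realizations (about 1.5 min); texture oracles run on ROIs up to 4×4×2,
surface oracles on masks up to 8³ — sizes at which exhaustive enumeration
is exact and fast.

## Known limitations

* The tolerance contract is evaluated on voxel-center surfaces; mesh-based
  (surfel) surface dice would weight by area and can differ near high
  curvature.
* At 1 mm spacing, τ = 1.18 mm admits only ±1 voxel of local change, so
  the perturbation space is finite and the realized deformation amplitude
  is bounded by τ − h/2; sub-voxel contour representations could explore
  more.
* Face-counted surface areas (and hence sphericity) carry the staircase
  bias described above.
* η is a ratio of dispersions, blind to systematic (bias-like) shifts a
  protocol might induce; only the segmentation component of the variance
  decomposition is simulated here — acquisition and processing terms enter
  `combine_variances()` as externally supplied numbers.
* The stability contrast is demonstrated on synthetic Gaussian features;
  with clinical data the same functions apply unchanged, but effect sizes
  and η values will be cohort-specific.
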