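# segstab

Segmentation uncertainty propagation for radiomic biomarkers.

## The problem

Radiomic features — quantitative descriptors of intensity, shape and texture
computed from a medical image inside a delineated region — are only as
reproducible as the delineation they are computed from. Tumor contours (the
gross tumor volume, GTV) are drawn by hand; two clinicians routinely disagree
by a millimeter or more along the tumor surface. A prognostic model built on
features from a single contour per patient can test as highly significant and
still be an accident of that particular set of contours.

`segstab` makes this uncertainty measurable. It is aimed at radiomics
researchers who want to stress-test a feature set or a prognostic model
before trusting it:

1. **Perturb** each binary tumor mask with a Monte Carlo sampler whose every
   realization stays within a surface-distance tolerance τ of the original
   contour (default τ = 1.18 mm, a published interobserver bound for lung
   GTVs), as a stand-in for plausible observer variability.
2. **Extract** IBSI-consistent radiomic features (first-order, shape, GLCM,
   GLRLM, GLSZM, GLDM, NGTDM; fixed 25 HU bins, 1 mm³ voxels) from every
   mask realization.
3. **Rank** each feature by its uncertainty-to-effect ratio

   η = median over patients of IQR(Xᵢ across realizations) /
       IQR(median of Xᵢ per patient across patients),

   the within-patient spread induced by segmentation noise relative to the
   between-patient spread the feature is supposed to detect. η near 0 means
   the feature barely notices contour noise; η near 1 means the noise is as
   large as the effect.
4. **Stress-test** a Cox proportional-hazards model with median
   stratification: resample one realization per patient, refit, score the
   test cohort and collect the log-rank p-value, many times. Report the
   fraction of realizations that stay significant, an ensemble model (the
   fit closest in least squares to the coefficient medians) with per-patient
   score averaging, and each patient's stratification agreement
   δ = (#majority − #minority)/(#majority + #minority) across realizations.

Volumes are read from NIfTI or NRRD with physical spacing; survival and
feature tables are plain CSV. A synthetic module (textured ellipsoid
phantoms, two-level Gaussian feature tables, proportional-hazards survival)
makes the entire pipeline runnable and testable without any clinical data.

## Worked example

```r
library(segstab)

## 1. perturb a tumor delineation within a 1.18 mm surface tolerance
ph  <- make_phantom(radius_mm = 10, seed = 1)   # 64^3 CT-like phantom + mask
cfg <- perturbation_config(tolerance_mm = 1.18, n_realizations = 30, seed = 1)
masks <- generate_realizations(ph$mask, cfg)
surface_distance_summary(ph$mask, masks[[1]], tau = 1.18)
#> <surface_distance_summary> max A->B 1.000 mm, max B->A 1.000 mm
#>   max symmetric 1.000 mm, mean symmetric 0.421 mm, surface dice 1.0000
all(vapply(masks, within_tolerance, TRUE, A = ph$mask, tau = 1.18))
#> [1] TRUE
range(vapply(masks, function(m) sum(m$voxels), 0))  # volumes do vary
#> [1] 4097 4415
```

Every realization is a single connected, hole-free mask whose boundary stays
within 1 mm of the original here — inside the 1.18 mm contract — while the
realized volumes span ±4%.

```r
## 2. features from one realization
round(extract_all(ph$image, masks[[1]], run_config())[core_feature_names()], 3)
#>                     firstorder_Maximum            gldm_GrayLevelNonUniformity
#>                                153.990                                688.706
#>           glrlm_GrayLevelNonUniformity                       ngtdm_Coarseness
#>                                308.933                                  0.001
#>                glszm_GrayLevelVariance                       glrlm_RunEntropy
#>                                 74.283                                  4.949
#>                               glcm_MCC glszm_GrayLevelNonUniformityNormalized
#>                                  0.903                                  0.100

## 3. eta: which features keep their effect under contour noise?
feats <- data.frame(name    = c("robust1", "robust2", "noisy1", "noisy2"),
                    mean    = 10, sigma_b = 1,
                    sigma_w = c(0.03, 0.08, 0.35, 0.45))
fr <- make_feature_table(n_patients = 200, n_realizations = 300, feats,
                         seed = 7)
eta_table(fr)
#>   feature        eta  numerator denominator defined
#> 4  noisy2 0.47467327 0.60177791    1.267773    TRUE
#> 3  noisy1 0.35395475 0.46804949    1.322343    TRUE
#> 2 robust2 0.07550699 0.10698274    1.416859    TRUE
#> 1 robust1 0.03105711 0.04011853    1.291766    TRUE
```

The estimated η recover the designed within/between noise ratios
(0.45, 0.35, 0.08, 0.03). `rank_features()` turns such a table into the
k most robust ("low η") and k most sensitive ("high η") feature sets.

```r
## 4. stability of a Cox median-stratification model under contour noise
st <- make_eta_contrast_study()        # twin low-/high-eta synthetic study
sim_low  <- run_simulation(st$fr_train_low,  st$surv_train,
                           st$fr_test_low,  st$surv_test, st$features,
                           n_sim = 200, seed = 1)
sim_high <- run_simulation(st$fr_train_high, st$surv_train,
                           st$fr_test_high, st$surv_test, st$features,
                           n_sim = 200, seed = 1)
sim_low
#> <simulation_result> 200 pipeline iterations (0 failed)
#>   fraction significant (p < 0.05): 0.930
#>   ensembled model log-rank p: 0.006026
#>   median patient agreement delta: 1.000
sim_high
#> <simulation_result> 200 pipeline iterations (0 failed)
#>   fraction significant (p < 0.05): 0.795
#>   ensembled model log-rank p: 0.009641
#>   median patient agreement delta: 0.711
```

Both setups carry the *same* prognostic signal and both are clearly
significant on the original contours (log-rank p ≈ 0.01). But once
realistic contour noise is resampled through the pipeline, the model built
on low-η features stays significant in 93% of realizations and classifies
the median patient identically in every realization (δ = 1.0), while the
high-η model drops to 80% and its median patient agreement falls to 0.71 —
the model's verdict on individual patients has become contour-dependent.

A thin command-line wrapper over the same functions is installed at
`inst/cli/segstab.R` (subcommands `surfdist`, `perturb`, `extract`, `eta`,
`simulate`).

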