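# kinhet — kinetic-heterogeneity subregion analysis and radiomics for breast DCE-MRI

Breast tumors mix three delayed-enhancement kinetics on dynamic
contrast-enhanced MRI — **persistent** (late signal keeps rising),
**plateau** (stable) and **washout** (falling; the most suspicious).
`kinhet` classifies every enhancing voxel of a tumor by its curve type,
partitions the lesion into the three kinetic subregions, quantifies their
mixing, and asks whether radiomic features of the *washout subregion*
predict molecular subtype (Luminal, HER2-enriched, HER2 status) better than
features of the whole tumor. It is aimed at quantitative-imaging
researchers who want a fully testable, data-free implementation of that
pipeline: a synthetic DCE phantom/cohort generator with voxel-level ground
truth drives every stage.

## The model

For each voxel, with pre-contrast `S0`, first post-contrast `S1` and last
post-contrast `Slast`:

* enhancing iff `(S1 - S0)/S0 > 0.5` (strict);
* with `r = (Slast - S1)/S1`: washout if `r < -0.10`, plateau if
  `|r| <= 0.10`, persistent if `r > +0.10`.

With `P = (P_washout, P_plateau, P_persistent)` the subregion proportions
and `k = 3`, the kinetic-heterogeneity entropy is

```
KH = - sum_i P_i * log_k(P_i)        (0 * log 0 := 0)
```

ranging from 0 (single component) to 1 (equal thirds). Per-tumor
parameters also include peak enhancement (max relative rise), enhanced
volume (mm³), and the predominant / worst curve type.

Downstream, the first post-contrast volume is resampled to 1 mm isotropic
(cubic B-spline), z-score normalized (×100) against a reference region,
and a pinned radiomic inventory is extracted per ROI — 1132 features for
the whole tumor, 1158 for the washout region (14 shape + 13 image types ×
{18 first-order, 22/24 GLCM, 14 GLDM, 16 GLRLM, 16 GLSZM}). LASSO-logistic
Radscore models (10-fold CV, λ at minimum binomial deviance) are fitted on
a stratified 7:3 split and evaluated with ROC/AUC, Youden operating
metrics and decision-curve analysis.

## Worked example

```r
library(kinhet)

ph  <- simulate_phantom(phantom_spec(class_proportions = c(0.3, 0.3, 0.4),
                                     noise_sd = 4, seed = 1))
sub <- segment_kinetics(ph$series, ph$mask)
kinetic_profile(ph$series, sub)
#>   peak_enhancement enhanced_volume washout_pct plateau_pct persistent_pct
#> 1            1.361            4552       30.34        27.9          41.76
#>   kinetic_heterogeneity predominant_type worst_type insufficient
#> 1                0.9855                3          1        FALSE

mean(sub[ph$mask == 1] == ph$truth[ph$mask == 1])
#> [1] 0.9993409
```

Read: of the 4552 enhancing voxels (4552 mm³ at 1 mm isotropic), 30.3% are
washout, 27.9% plateau, 41.8% persistent — close to the simulated mixture
(0.3/0.3/0.4). KH = 0.986 says the tumor is nearly maximally heterogeneous.
The predominant type is persistent (3); the worst type is washout (1),
since washout is present. At noise SD 4 the voxel classification agrees
with the simulated ground truth at 99.9% of tumor voxels (100% at zero
noise — a tested invariant).

## Analysis workflow

The numbered scripts under `analysis/` are thin drivers over the package:

1. `01_simulate_cohort.R` — simulate the phantom cohort (ground truth to
   `results/cohort_ground_truth.csv`, one example phantom as NIfTI under
   `scratch/`).
2. `02_kinetic_heterogeneity.R` — segment subregions, compute kinetic
   parameters, score agreement with ground truth.
3. `03_radiomics_features.R` — extract the 1132-feature whole-tumor and
   1158-feature washout inventories from normalized volumes.
4. `04_subtype_models.R` — fit and evaluate washout vs whole-tumor LASSO
   Radscore models on three emulated subtype tasks (124 patients, 87/37
   split), with ROC and decision curves.

## Acceptance script

`scripts/acceptance.R` recomputes, from scratch with the installed package,
the closed-form quantities of the kinetic-heterogeneity index: the maximum
of KH over the k = 3 probability simplex on a 0.01-step grid, and the KH of
a single-component tumor obtained by running a noiseless one-component
phantom through the full segmentation pipeline.

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
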