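---
title: "Kinetic-heterogeneity subregion analysis of breast DCE-MRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic-heterogeneity subregion analysis of breast DCE-MRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Breast tumors are kinetically heterogeneous: after contrast injection,
different parts of the same lesion enhance and then evolve differently.
Clinical breast-MRI reporting distinguishes three delayed-enhancement
patterns — **persistent** (late signal keeps rising), **plateau** (late
signal stable) and **washout** (late signal falls), with washout the most
suspicious. Averaging radiomic features over the whole tumor dilutes this
internal structure. `kinhet` implements the alternative: classify every
enhancing voxel by its kinetic curve type, carve the tumor into the three
corresponding subregions, quantify the mixing of curve types with a
normalized entropy, and build predictive models from features of the
washout subregion alone, compared head-to-head with whole-tumor models.

Because the underlying patient cohort is not publicly deposited, the
package is driven end-to-end by a synthetic phantom and cohort generator
with known voxel-level ground truth. Everything downstream of data
acquisition is implemented and testable; nothing in the package depends on
access to the original scans.

# Voxel classification model

The classifier reads three volumes of a dynamic series: pre-contrast
$S_0$, first post-contrast $S_1$, and last post-contrast $S_{last}$
(the emulated protocol acquires 1 pre + 8 post phases).

1. **Enhancement gate.** A voxel inside the tumor mask is *enhancing* iff
   $(S_1 - S_0)/S_0 > 0.5$, a strict inequality ("over 50%"). Voxels with
   $S_0 \le 0$ or non-finite values are excluded and counted in a quality
   report, never classified.
2. **Late-change classification.** For enhancing voxels,
   $r = (S_{last} - S_1)/S_1$. Then $r > +0.10$ is persistent (code 3),
   $r < -0.10$ washout (code 1), and the **closed** band
   $r \in [-0.10, +0.10]$ plateau (code 2). The strict/closed conventions
   mirror the wording "more than 10%" / "within a 10% range"; the codes
   follow the suspiciousness ordering washout < plateau < persistent.

Both rules are ratios with the *earlier* phase in the denominator, so the
subregion map is invariant under any global intensity scaling $c > 0$ — a
property the test suite asserts. For the same reason classification runs on
**raw** intensities: a z-score normalization shifts the origin and would
corrupt the ratios. Normalization is applied only to the volumes feeding
feature extraction, via a single per-patient affine map.

# Kinetic-heterogeneity parameters

With $P_1, P_2, P_3$ the proportions of washout, plateau and persistent
voxels among the enhancing ones and $k = 3$ categories, the
kinetic-heterogeneity entropy is

$$\mathrm{KH} = -\sum_{i=1}^{k} P_i \log_k P_i, \qquad 0\log 0 := 0 ,$$

which ranges over $[0, 1]$: 0 when the enhanced region holds a single
component, 1 at equal thirds. We keep $k$ fixed at 3 rather than setting it
to the number of non-zero components: the alternative would score any
two-component 50/50 tumor as maximally heterogeneous ($\mathrm{KH}=1$),
contradicting the interpretation of the index as distance from
single-component homogeneity.

The remaining per-tumor parameters: **peak enhancement** — the maximum of
$(S_1-S_0)/S_0$ over enhancing voxels (we use the scale-free ratio; a raw
signal maximum would depend on scanner scaling); **enhanced volume** —
enhancing-voxel count times physical voxel volume, in mm³; **predominant
type** — arg-max of $P$, ties toward the more suspicious type; **worst
type** — the most suspicious type present at any proportion. Tumors with no
enhancing voxels yield a missing profile (flagged `insufficient`), not a
zero-filled one, mirroring the exclusion of cases whose CAD output cannot
be analyzed.

# Preprocessing

* **Resampling** to 1 mm isotropic voxels with true separable cubic
  B-spline interpolation (causal/anti-causal prefilter, pole
  $\sqrt{3}-2$, mirror boundary); masks and label maps use nearest
  neighbour and keep their exact label sets. Output size per axis is
  `round(n * spacing / target)`, preserving physical extent to within a
  voxel.
* **Intensity normalization** $x \mapsto (x - \mu_{ref})/\sigma_{ref}
  \times 100$ against a reference-region mask (pectoralis muscle in the
  clinical pipeline; a tumor-free corner in the phantoms). The source
  protocol's "bin width 25 HU" is not meaningful for MRI; we adopt the
  conventional pairing of z-score $\times$ 100 with fixed bin width 25,
  i.e. a quarter of a reference standard deviation per bin.
* Denoising/"enhancement" and template registration are named by the
  source protocol without parameters; they are deliberately omitted
  non-goals rather than guessed.

# Radiomic features

The inventory is pinned by construction: 14 shape features on the original
geometry plus, per image type, 18 first-order, 22 *or* 24 GLCM, 14 GLDM, 16
GLRLM and 16 GLSZM features over a 13-image bank (original, LoG at
$\sigma = 1,2,3,4$ mm, and the 8 sub-bands of a single-level undecimated
3-D Haar wavelet). Hence

$$14 + 13\,(18 + 22 + 14 + 16 + 16) = 1132, \qquad
  14 + 13\,(18 + 24 + 14 + 16 + 16) = 1158 .$$

The two GLCM counts reproduce the whole-tumor (1132) and washout-region
(1158) runs of the study design; the 22-set drops `SumAverage` (redundant
with `JointAverage` under symmetric matrices) and `MCC`. The exact identity
of the two features, the LoG scales and the wavelet family are not stated
in the source — they are config-pinned here, and only the counts are
treated as ground truth.

Numerical conventions worth knowing:

* Discretization is fixed-bin-width, **anchored at the ROI minimum** of
  each derived image, so adding a constant to the whole image leaves every
  texture feature unchanged (tested).
* Texture matrices aggregate in 3-D over the 13 unique distance-1
  directions; GLCM and GLRLM are merged (summed) across directions before
  features are computed. GLSZM zones and the largest-cluster rule use
  26-connectivity, the 3-D CAD convention (6-connectivity is available).
* Degenerate guards: a constant ROI has one gray level; entropy-type
  features are exactly 0, GLCM `Correlation`/`MCC` are defined as 1.
* **Shape features use voxel representations**: volume is voxel count ×
  voxel volume and surface area counts exposed voxel faces (no mesh
  library is available in the environment). The face-count estimator does
  not converge to the true surface area — for a ball it tends to 1.5× the
  sphere area, so the sphericity of a digital ball tends to 2/3 rather
  than 1. Tests therefore pin the estimator's own analytic limits (exact
  on cubes; 2/3 on balls) instead of the mesh values a marching-cubes
  extractor would give. Comparisons *between* ROIs with the same estimator
  remain meaningful.

# Models and evaluation

Per binary task (Luminal vs rest, HER2-enriched vs rest, HER2-positive vs
negative — Basal-like is excluded, mirroring the source's sample-size
exclusion):

1. **Split** 7:3 (124 → 87/37, nearest-integer on the training count),
   stratified by outcome. Stratification is a design choice here — the
   source says only "randomly" — so that 37-patient test sets retain both
   classes.
2. **Screening** on training rows only: zero-variance removal always;
   optionally a two-sided Mann-Whitney filter at $p < 0.05$ (the source's
   own two-group test choice; its screening procedure is otherwise
   unspecified). Every removal is logged.
3. **LASSO-logistic** via 10-fold cross-validation (glmnet), $\lambda$ at
   minimum mean binomial deviance, refit on the full training set;
   features with non-zero coefficients form the signature.
4. **Radscore** $= \beta_0 + \sum_j \beta_j x_{ij}$ on
   training-standardized columns. The intercept is included (the source
   is ambiguous); it shifts all scores equally and cannot affect ROC or
   DCA ordering.
5. **Evaluation**: AUC as the rank statistic (ties ½) with a DeLong-type
   asymptotic 95% CI; sensitivity, specificity, PPV, NPV and accuracy at
   the Youden-optimal cutoff (`score >= cutoff` predicts positive;
   the scan covers every observed score); decision curves
   $NB(p_t) = TP/n - FP/n \cdot p_t/(1-p_t)$ from logistic-calibrated
   probabilities, with treat-all and treat-none references.

No test-row information can reach the model: screening, standardization and
$\lambda$ selection see training rows only, and the suite verifies that
permuting test rows leaves the fitted model bit-identical.

# The synthetic world

`simulate_phantom()` builds an ellipsoidal tumor (optional lobulation via a
low-order spherical-harmonic radius perturbation, which keeps the mask
star-shaped and hence connected) on a 1 mm isotropic grid, assigns each
in-mask voxel an archetype drawn from configurable class proportions, and
synthesizes a 9-phase series. Archetypes enhance by 100% at $S_1$
(comfortably above the 50% gate) with late slopes $-30\%/0\%/+30\%$ —
comfortably outside the ±10% band, so moderate noise cannot flip classes.
Intermediate post phases are linear in phase index: the classifier reads
only pre/first/last, so intermediate shape is immaterial. Background voxels
enhance 10%, below the gate. Noise is additive i.i.d. Gaussian
(SD 4 signal units at baseline 100 in the workflow scripts — a mid-range
SNR choice; the source gives no noise model, so this is a free parameter of
the synthetic world, not a calibrated one). Rician noise, pharmacokinetic
(Tofts) curve shapes, motion and B1 artifacts are explicit non-goals.

`simulate_feature_cohort()` stands in for the patient feature matrices:
i.i.d. standard-normal features with a standardized mean difference on a
designated informative subset, labels Bernoulli at a set prevalence.
`simulate_paired_roi_cohort()` creates the two-ROI regime of interest —
signal only in the washout-region table — under which the washout model
should, and in the tests does, beat the whole-tumor model on held-out AUC
in ≥ 80% of seeds.

What a green suite establishes: the machinery — classification rules,
entropy, inventory, split arithmetic, leak-free model path, ROC/DCA
identities — is correct on a world where ground truth is known. What it
does not establish: the cohort-specific AUCs of the original study, which
are unreproducible without the patient data and are out of scope.

# Worked example

```{r, eval = FALSE}
library(kinhet)

ph  <- simulate_phantom(phantom_spec(class_proportions = c(0.3, 0.3, 0.4),
                                     noise_sd = 4, seed = 1))
sub <- segment_kinetics(ph$series, ph$mask)
kinetic_profile(ph$series, sub)

mean(sub[ph$mask == 1] == ph$truth[ph$mask == 1])  # voxel agreement
```

The numbered scripts under `analysis/` run the full workflow (cohort
simulation, segmentation and parameters, two-ROI feature extraction,
model comparison) and write their tables under `results/`.

# Known limitations

* Shape features are voxel-based, not mesh-based (documented bias above).
* GLCM/GLRLM merge matrices across directions rather than averaging
  per-direction features; values can differ slightly from extractors that
  average (feature counts and invariances are unaffected).
* The synthetic cohort's feature tables are Gaussian and independent
  across features; real radiomic features are heavily correlated. The
  model-pipeline properties tested here (null behaviour, leak-freedom,
  ROI-signal recovery) do not depend on that correlation structure, but
  selected-signature sizes on real data will differ.
* Univariate CIs use the asymptotic DeLong variance; at test-set sizes of
  a few dozen they are approximate.
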