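---
title: "Methods: radiomics survival modeling in radsurv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiomics survival modeling in radsurv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radsurv)
```

## The problem

Surgically resected grade 1–2 pancreatic neuroendocrine tumors (PanNETs)
have heterogeneous outcomes: most patients do well, but roughly one in
eight recurs or dies within the first decade, and the AJCC anatomic stage
only partly separates these groups. `radsurv` implements a
contrast-CT radiomics pipeline for this setting: quantitative texture and
shape features are extracted from the segmented tumor volume of interest
(VOI), distilled into a single linear risk score (the *R-score*), and
combined with age and stage in Cox proportional-hazards models whose
incremental value is quantified on censored survival data.

Because real patient images cannot ship with a package, `radsurv` includes
a first-class synthetic-data module that generates tumor phantoms, reader
variability and Cox-linked outcomes with known ground truth. Every stage of
the pipeline is exercised and tested against these phantoms.

## Image model and preprocessing

A phantom (`phantom_spec()`, `generate_tumor_volume()`) is an ellipsoidal
tumor (semi-axes in mm) on an anisotropic voxel grid, default
64 × 64 × 32 voxels at 1 × 1 × 3 mm — the uniform grid to which all images
are resampled before feature extraction (`resample()`, trilinear for the
image, nearest-neighbour for the mask). Intra-tumoral texture is a
Gaussian random field: white noise convolved with a Gaussian kernel of a
stated correlation length (default 3 mm) and scaled to a stated amplitude
(SD in HU). The field's smoothness and amplitude directly modulate GLCM
entropy and contrast, which is exactly the axis along which the prognostic
signal of the published signature lies. Tumor enhancement defaults
(110 HU tumor on 60 HU background, noise SD 5 HU, amplitudes log-normal
with median 15 HU) are a free design choice — the source study publishes no
intensity distributions — picked to resemble arterial-phase hypervascular
PanNETs; they are deliberately not tuned per experiment.

Filtered feature variants use a millimetre-parameterized separable
Gaussian (`gaussian_filter()`) and Laplacian-of-Gaussian (`log_filter()`,
Gaussian smoothing followed by a finite-difference Laplacian per mm²), with
mirror padding to avoid edge artifacts in small VOIs. Default scales are
1 mm (Gaussian) and 2 mm (LoG); the source study does not print its filter
scales, so these are declared defaults, configurable per
`transform_tag()`.

Gray levels are discretized with a **fixed bin count** (default 32) over
the in-mask intensity range. The study's exact normalization/discretization
settings live in an unavailable supplement; fixed bin count is the
IBSI-recommended default for this situation and has the useful consequence
that all texture features are invariant to affine rescaling of the in-mask
intensities (verified by property tests).

## Feature families

`extract_all()` computes, per phase (arterial AP / portal-venous PVP) and
transform (N/G/LOG):

* **morphology** (mask-only, phase token `MASK`): volume (voxel count ×
  voxel volume) and flatness. Flatness is the bounded IBSI convention
  `sqrt(λ_least / λ_major)` of the principal-component eigenvalues of the
  physical voxel coordinates, in (0, 1], even though the prose convention
  ("ratio of major to least axis length") is its reciprocal; the bounded
  form keeps scores well defined and only reverses monotonicity.
* **first-order** statistics of the in-mask intensities, including the
  robust mean absolute deviation (mean |x − mean| over values inside the
  closed [P10, P90] range).
* **GLCM**: symmetric co-occurrence at Chebyshev distance 1 over the 13
  unique 3D directions, per-direction normalized matrices averaged (IBSI
  "averaging" merger), in-mask pairs only. Entropies use log base 2.
* **GLSZM / GLDZM**: 26-connected equal-level zones; zone distance is the
  minimum in-mask Chebyshev distance to the mask border (border voxels = 1,
  computed by multi-source BFS, equivalent to iterated erosion).
* **NGLDM**: dependence count = number of equal-level in-mask 26-neighbours
  (coarseness threshold α = 0, counts 0–26); emphasis features dividing by
  the count use (k + 1).

Zone connectivity ignores spacing anisotropy (voxel-topology definition).
The registry is configurable; the full default registry yields ~460
features per subject across both phases, a realistic dimensionality for the
selection cascade. The study's exact 692-feature inventory is not
recoverable and is not a target; what is preserved is the cascade's
bookkeeping contract. All families are validated to 1e-9 relative
tolerance against brute-force enumerations on small random VOIs.

## Selection cascade and the R-score

`run_selection()` mirrors the three published stages:

1. **Reliability**: features with Lin's concordance correlation
   coefficient (population-moment form) below 0.8 between two readers'
   extractions are removed (strictly `< 0.8`; the boundary is retained).
   The second reader is simulated by `perturb_mask()`, which displaces the
   mask boundary by a smooth random field scaled in millimetres.
2. **Redundancy**: while any pairwise |Pearson r| exceeds 0.9, the member
   of the worst pair with the larger mean absolute correlation is dropped.
   The retained set has max |r| ≤ 0.9. Which member of a pair is dropped is
   not specified in the source; the mean-absolute-correlation rule is the
   standard correlation-analysis heuristic.
3. **LASSO-Cox** (`fit_lasso_cox()`, via glmnet, Breslow ties): the
   penalty is chosen by 10-fold cross-validated partial-likelihood
   deviance, folds stratified by event status and seeded. The default rule
   is the deviance-minimizing λ; the 1-SE rule is available. The λ path is
   floored at 5% of λ_max because with ~10% event rates the unpenalized end
   of the path is quasi-separated and never competitive.

Features are standardized to mean 0 / SD 1 before penalization; the
training means and SDs are frozen and reapplied verbatim to any test set
(the source does not state this explicitly; it is the only leakage-free
contract). The accounting identity `retained = total − unreliable −
redundant` is enforced structurally by `selection_report()`.

The R-score (`compute_rscore()`) is the inner product of the standardized
feature vector with the signature coefficients. Two provenances satisfy the
same contract: `fitted` (from the LASSO) and `published` — the 15-term
definition shipped verbatim as a data asset (`published_rscore()`), whose
largest coefficient (0.656) belongs to arterial-phase joint entropy.

## Survival models and evaluation

The clinical model (C-model) is a Cox regression on age (linear per year)
and AJCC stage as indicators against stage I; the clinical-radiomics model
(CR-model) adds the R-score (`build_models()`; `survival::coxph`, Breslow
ties, Breslow baseline stored for absolute risk). Evaluation
(`evaluate_models()`) reports:

* **Harrell's C-index** over usable pairs, with subject-level percentile
  bootstrap CIs, and paired-bootstrap comparison of two models
  (`compare_cindex()`; the source reports a p-value without naming the
  test — the paired bootstrap with a normal approximation is the documented,
  seedable choice here).
* **Time-dependent AUC** (cumulative cases / dynamic controls) with
  inverse-probability-of-censoring weights from the reverse Kaplan–Meier
  estimator.
* **Survival NRI and IDI** at a fixed horizon (default 36 months),
  category-free, with IPCW status weights; predicted event probabilities
  come from each Cox model's own Breslow baseline, so models are compared
  on the probability scale.
* **Calibration**: quantile risk groups, mean predicted S(t) vs the
  Kaplan–Meier estimate with Greenwood log-log CIs; empty bins merge with
  a neighbour.

An optimal risk cutoff (`select_cutoff()`) scans midpoints of sorted
unique scores, defines 3-year status only for subjects whose status is
known at the horizon (plain exclusion of earlier censorings, matching the
plain sensitivity/specificity rule of the source rather than an IPCW
variant), and maximizes sensitivity + specificity subject to both
exceeding 60%, breaking ties toward the lower cutoff.

## Outcome generator and study conditions

Outcomes follow a Weibull-baseline proportional-hazards model: the linear
predictor combines the standardized texture-field amplitude, centered age
and stage via `true_beta`, and event times are inverted from uniform draws.
Censoring is administrative at 120 months only. The default coefficients
(amplitude 0.8 per SD; age 0.02 per year; stage II/III/IV 0.7 / 1.4 / 2.0,
monotone as in the published stage hazard ratios) and the default stage mix
(40 / 48 / 9 / 3%) and age distribution (53 ± 12 years) emulate the
development cohort's structure. The baseline Weibull scale (1300 months,
shape 1.2) was solved once, by numerical integration over the covariate
distribution, so the marginal event fraction is ~13.2% — the development
set's printed event rate; it is a fixed study condition, not a per-test
dial. Generators return their latent parameters (amplitude, its
standardized value, the true linear predictor) so recovery tests are
assertable, and identical seeds give bit-identical outputs.

What the phantoms do **not** emulate: anatomical context (pancreas,
vessels), contrast kinetics, scanner-specific noise texture, and
real-reader systematic bias (the simulated second reader differs only by a
smooth boundary displacement). Passing tests therefore demonstrate the
correctness and internal consistency of the pipeline's mathematics and its
leakage-free validation discipline — not clinical performance on patient
images.

## Numerical and design choices

* Discretization level = `1 + floor(n_bins (x − min)/(max − min + ε))`
  clipped to `n_bins`; a constant VOI maps to level 1.
* Degenerate guards: empty masks error; coplanar masks have undefined
  flatness and error; constant features error in `standardize()` and warn
  (and are dropped first) in the redundancy filter; Cox fits error on
  non-convergence or separation rather than returning silent garbage.
* GLCM correlation of a constant VOI is defined as 1 (zero-variance limit).
* The C-index point estimate is computed by `survival::concordance`
  (reverse orientation); the test suite cross-checks it against an
  independent exhaustive pair enumeration, and all other estimators
  (IPCW AUC, NRI, IDI) are implemented directly from their definitions.
* All Monte Carlo components (fold assignment, bootstrap, phantoms) draw
  from explicit seeds; `with_seed` scoping restores the caller's RNG
  state.

## Problem sizes used in the shipped experiments

The test suite runs the full image pipeline end to end on cohorts of a few
dozen 32³-scale phantoms, and the discrimination experiment on 300
development / 250 test / 400 null-cohort subjects with the default
64 × 64 × 32 grids — sizes chosen so the whole suite completes in minutes
on a laptop while leaving the Monte Carlo error of each assertion well
inside its tolerance. The bootstrap default is 1000 replicates in
interactive use and a few hundred inside the tests.

## Known limitations

* The feature registry, while IBSI-shaped, is not byte-compatible with any
  specific extraction software; published-signature scoring on real data
  would require harmonizing feature definitions and discretization.
* NRI/IDI p-values use a bootstrap normal approximation; perturbation
  resampling (as in some reference implementations) is not provided.
* The GLDZM distance map uses in-mask (geodesic) Chebyshev propagation;
  for highly non-convex masks this differs from the free Euclidean
  distance.
* Wavelet transforms, 2D slice-wise features and competing-risk endpoints
  are out of scope.
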