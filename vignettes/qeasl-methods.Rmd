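---
title: "Volumetric tumor-response assessment and survival analysis with qeasl3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric tumor-response assessment and survival analysis with qeasl3d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qeasl3d)
```

## The problem

Transarterial chemoembolization (TACE) devascularizes hepatocellular
carcinoma (HCC) rather than shrinking it, so diameter-based response criteria
(RECIST and relatives) misread treatment effect. The quantitative EASL
(qEASL) approach instead measures the *enhancing* tumor volume in 3D: tissue
that still takes up contrast between the unenhanced and arterial-phase
T1-weighted MR acquisitions is taken as viable, and response is judged by the
change of that volume across treatment sessions. `qeasl3d` implements this
measurement chain end to end — phase subtraction, parenchyma reference-ROI
normalization, enhancing-voxel classification, volumetry in cm³, CR/PR/SD/PD
categorization over repeated sessions, and the survival comparison of
responders versus non-responders — together with synthetic phantoms and
cohorts carrying voxel-exact ground truth so that every stage is testable.

## The measurement model

All images of one session must live on an identical grid (shape, spacing,
origin within 1e-6 mm); the package performs no registration and treats a
mismatch as a hard error. Voxel indices are 1-based in R and physical
coordinates refer to voxel centers; volumes are always physical:
`prod(spacing)/1000` cm³ per voxel.

1. **Subtraction.** `subtract_phases()` computes voxelwise
   `arterial − unenhanced`. Negative values (noise) are retained; clipping
   would bias the reference statistics.
2. **Reference ROI.** `realize_roi()` places a ball of target volume 1 cm³
   (radius `(3V/4π)^{1/3}` ≈ 6.20 mm) in non-tumor parenchyma; it must lie
   fully inside the image and intersect no lesion mask. `roi_stats()` returns
   the mean and *population* SD of the subtracted intensities over the ROI
   (for the ≈1000-voxel ROIs of typical spacing the n vs n−1 distinction is
   far below any tolerance used here).
3. **Enhancing-voxel rule.** A tumor voxel is enhancing when its subtracted
   intensity exceeds `ROI mean + k · ROI SD`. The cutoff multiplier `k`
   defaults to 2.0, the convention in the quantitative-EASL literature; it is
   an explicit `qeasl_config()` field and is recorded in every measurement
   row, because the underlying software ecosystem does not standardize it. An
   alternative convention — thresholding relative enhancement as a percentage
   of the ROI mean — exists in the field; only the mean + k·SD form is
   implemented, and `k` is the single dial.
4. **Volumetry.** `measure_lesion()` reports whole-tumor and enhancing-tumor
   volume; `enhancing ≤ whole` holds by construction. Two readers' volumes
   are averaged by `average_readers()` (volumes are pooled, never categories,
   so reader disagreement on the category is resolved upstream of
   classification). `color_map()` renders the viable (red) / necrotic (blue)
   partition as a NIfTI overlay.

The interactive "balloon" used to refine segmentations in clinical software
is proprietary; `balloon_refine()` provides a physical-space surrogate:
morphological dilation/erosion by a ball of radius `|delta|` mm honoring
anisotropic spacing. It is labelled a surrogate — tests rely on its
mathematical properties (identity at 0, monotonicity, near-idempotence of
dilate-then-erode), not on equivalence to any particular product.

## Response criteria and session logic

With `S_ref` and `S_post` the summed enhancing volumes of the target lesions
(at most 2 per patient: therapy-naive, artifact-free, diameter > 1 cm;
largest first, ties by id):

* **CR** — `S_post ≤ cr_epsilon_cm3` (default 0: literal disappearance of all
  enhancing tissue; the epsilon exists to absorb single-voxel noise when the
  user asks for it);
* **PR** — change ≤ −65%; **PD** — change ≥ +73% (both bounds closed:
  −65.0% is PR, +73.0% is PD); **SD** — neither.

Responder means CR or PR. Percent change from a zero reference is undefined;
reappearing enhancement is classified PD directly, and 0 → 0 is sustained CR.

Each session is judged against the most recent pre-session imaging
(`reference_mode = "previous"`), so a second-session response is a ≥65% drop
from the post-first-session volume; judging every session against the
original baseline is available as `reference_mode = "baseline"` and the same
switch governs sessions beyond the second. A repeat treatment counts toward
*secondary response* only when delivered within 3 months of the initial
non-response (months of 30.4375 days; dates ISO-8601); later retreatments are
flow-labelled `excluded_window`, and missing response imaging is
`lost_followup`. New non-target lesions do not influence the category — the
criteria are defined on the target-lesion sum only.

## Survival analysis

Overall survival runs from the first treatment to death from any cause.
`km_fit()` is the product-limit estimator; the median is the earliest time
with `S(t) ≤ 0.5` and its 95% CI comes from inverting pointwise log(−log)
bands (Brookmeyer–Crowley style, via `survival::survfit`). `logrank_test()`
is the standard two-group test; `cox_fit()` maximizes the partial likelihood
with **Breslow** tie handling (chosen for hand-verifiability — the test suite
checks a 4-record tied toy against a brute-force likelihood grid) and reports
Wald CIs; CIs are always recomputed by the model actually fitted, never
copied between univariate and multivariate fits. `cox_screen()` enters
covariates with univariate p < 0.10 (configurable) into the joint model.
Fisher's exact test is computed in-package by hypergeometric enumeration
(two-tailed by the point-probability rule; zero-margin tables give p = 1 by
convention) and is verified exhaustively against a brute-force oracle.

Patients alive or lost to follow-up are right-censored by default. A
`censoring_mode = "drop_censored"` replication mode removes them instead —
some retrospective analyses have done exactly that — but it conditions on the
future and biases the curves, so it is never the default.

## What the synthetic data emulate — and what they do not

`generate_phantom()` builds two-phase volumes containing spherical lesions
whose enhancing compartment is a concentric outer shell (the rim-enhancement
appearance after embolization), hit *exactly* by voxel count: truth volumes
are voxel-countable, never analytic approximations. Intensity defaults:
parenchyma 200 gaining 100 in the arterial phase, tumor 160, viable tumor
gaining 4 × the parenchyma gain, necrotic tissue gaining nothing. Noise is
additive Gaussian per phase with SD defaulting to half the parenchyma
contrast gain — a moderately noisy acquisition under which the k = 2 cutoff
sits ≈2.2 subtracted-noise SDs below the viable-tumor mean, giving an
expected one-sided loss of ≈1% of enhancing voxels (the test suite bounds
the recovery error at 5% over 20 seeds). Rician MR noise, realistic liver
anatomy, motion and field inhomogeneity are out of scope; passing phantom
tests therefore demonstrates correctness of the measurement chain, not
clinical performance on real scans.

`generate_trajectory()` emits per-session volume sums that provably classify
to a requested category sequence (draws stay well inside the category bands);
a PR or SD request immediately after CR is rejected as contradictory.
`generate_cohort()` ties it together: session-1 categories drawn from
CR/PR/SD/PD = 0.032/0.266/0.606/0.096, non-responders retreated after a
log-normal interval with median 0.8 months truncated to [0.1, 3], a 34.9%
session-2 response probability, exponential survival with responder median
47.8 months and a proportional-hazards multiplier (default 2.8) on final
non-responders, and independent exponential censoring calibrated to a target
censoring fraction (default 0.36). These set-points are the observed
operating characteristics of a 94-patient intermediate-stage HCC TACE series;
they make the simulator's flow tables and survival contrasts realistic at
cohort scale. The exponential baseline is the simplest PH-consistent choice;
the CR share among secondary responders (0.1) and the PD share among
persistent non-responders (0.25) are fixed once from the same series' flow
counts.

## Worked example

```{r example}
co <- generate_cohort(cohort_sim_spec(n_patients = 94, seed = 7))
report <- run_full(run_config(seed = 7), co$patients)
report
```

At 94 patients a true hazard ratio of 2.8 is estimated with wide error bars —
single-cohort log-rank p-values range from <0.01 to >0.1 across seeds — which
is exactly why parameter-recovery checks in the test suite use n = 1000 (Cox)
and 1000 replicates (log-rank type-I error), while the phantom volumetry
checks use 48×48×40 grids with a 12 mm lesion: large enough for sub-2%
recovery error, small enough that the whole suite runs in seconds.

## Numerical choices and edge cases

* Grid equality tolerance 1e-6 mm; NIfTI affines with rotation, shear or
  axis flips are rejected rather than silently resampled.
* Ball offsets for morphology and ROI realization include voxels at exactly
  the radius (tolerance 1e-9 mm²) so results are deterministic.
* Erosion that empties a non-empty mask returns the empty mask with a
  warning and an `emptied` attribute — volumetrically meaningful (CR-level),
  so not an error.
* Enhancing-shell assignment breaks distance ties by linear voxel index,
  making phantoms bit-reproducible under a seed.
* `percent_change(0, 0)` is 0 by definition; `percent_change(0, x>0)` is NA
  and classified PD.
* Fisher's two-tailed sum uses a relative tolerance of 1e-7 on the point
  probability to absorb floating-point ties, matching exact enumeration on
  every table with total ≤ 30.

## Limitations

The phantom generator validates the measurement chain, not segmentation
accuracy on real anatomy; DICOM ingestion, registration, perfusion modeling,
washout analysis and competing risks are out of scope. Response criteria
other than qEASL (mRECIST, 1D/2D EASL) are deliberately not implemented.
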