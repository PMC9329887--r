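# qeasl3d

Volumetric (3D) tumor-response assessment for hepatocellular carcinoma (HCC)
treated with transarterial chemoembolization (TACE), and the survival
analysis that follows from it. TACE devascularizes tumors rather than
shrinking them, so the clinically meaningful quantity is the **enhancing
(viable) tumor volume**: tissue that still gains signal between the
unenhanced and arterial-phase T1-weighted MR acquisitions. `qeasl3d` is for
imaging scientists and interventional-oncology researchers who need that
measurement chain as inspectable, tested code rather than a black-box
workstation.

## What it computes

Given co-registered unenhanced and arterial T1 volumes (NIfTI), a lesion
segmentation mask, and a reference region in non-tumor liver parenchyma:

1. voxelwise subtraction `arterial − unenhanced`;
2. a 1 cm³ spherical parenchyma ROI giving reference mean `μ` and SD `σ`;
3. enhancing-voxel rule: voxel `v` in the tumor is viable iff
   `sub(v) > μ + k·σ` (default `k = 2`);
4. whole-tumor and enhancing-tumor volumes in cm³ (voxel count × voxel
   volume), averaged over independent readers;
5. per-session qEASL categories on the summed enhancing volume `S` of up to
   two target lesions: **CR** if `S_post = 0`, **PR** if the change is
   ≤ −65 %, **PD** if ≥ +73 %, else **SD** (closed bounds); responder = CR
   or PR, with secondary responders defined by response to a repeat session
   delivered within 3 months;
6. Kaplan–Meier / log-rank / Cox (Breslow ties) comparison of overall
   survival between responders and non-responders, plus Fisher's exact,
   chi-square and Welch t tests for the descriptive tables.

A synthetic module generates multiphasic phantoms with voxel-exact truth
volumes, volume trajectories realizing any requested category sequence, and
longitudinal cohorts whose survival depends on response through a
proportional-hazards effect — the ground truth against which the whole
pipeline is validated.

## Worked example

Measure a noisy phantom lesion (truth: whole 14.147 cm³, enhancing
5.659 cm³):

```r
library(qeasl3d)
ph <- generate_phantom(phantom_spec(seed = 17))
measure_lesion(ph$arterial, ph$unenhanced, ph$masks$L1, roi_spec(ph$roi_center))
#>  lesion_id session_id reader_id whole_volume_cm3 enhancing_volume_cm3 roi_mean
#>         L1          1   reader1            14.15                5.607    98.58
#>  roi_sd roi_n enhancement_k
#>   69.92   997             2
```

The whole-tumor volume is exact (mask voxel count × voxel volume); the
enhancing volume is recovered within 1 % despite per-phase noise at half the
parenchyma contrast gain, because the `k = 2` cutoff sits well below the
viable-tumor enhancement.

Run a full synthetic cohort through classification, flow tabulation and
survival comparison:

```r
co <- generate_cohort(cohort_sim_spec(n_patients = 94, seed = 7))
run_full(run_config(seed = 7), co$patients)
#> qEASL cohort run
#> run_config: k=2, PR<=-65%, PD>=+73%, censoring=censor, reference=previous, seed=7
#> patients: 94; sessions assessed: 159
#>
#>   initial_responder secondary_responder       non_responder     excluded_window
#>                  29                  25                  40                   0
#>       lost_followup
#>                   0
#>
#> responders:      Kaplan-Meier: n=54, events=37, median OS 44.72065 months (95% CI 28.50739-59.58222)
#> non-responders:  Kaplan-Meier: n=40, events=22, median OS 21.61221 months (95% CI 14.07868-25.98141)
#> log-rank: chisq=1.761, p=0.1845
#> Cox non-response HR=1.452 (95% CI 0.835-2.526), p=0.1867
```

29 of 94 patients respond to the first session and 25 initial non-responders
respond to a within-window second session; the responders' median overall
survival is roughly double the non-responders' (the cohort was simulated with
a non-response hazard ratio of 2.8 — at n = 94 a single cohort estimates it
with wide error bars, which is why the test suite checks recovery at
n = 1000).

See `vignettes/qeasl-methods.Rmd` for the measurement model, parameter
rationale, and what phantom validation does and does not demonstrate.

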