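Package: qeasl3d
Title: Quantitative 3D Tumor-Response (qEASL) Analysis for Intra-Arterial Liver Cancer Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Volumetric assessment of hepatocellular carcinoma response to
    transarterial chemoembolization (TACE) from multiphasic contrast-enhanced
    MR volumes. Implements arterial-minus-unenhanced phase subtraction,
    parenchyma reference-ROI normalization, enhancing-voxel classification,
    whole- and enhancing-tumor volumetry in cubic centimeters, qEASL
    CR/PR/SD/PD response categories over repeated treatment sessions, and the
    downstream survival comparison of responders versus non-responders
    (Kaplan-Meier, log-rank, Cox proportional hazards). Ships a synthetic
    phantom and cohort generator with voxel-exact ground truth for validating
    every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    survival,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
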