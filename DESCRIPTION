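Package: alpsocm
Title: Glymphatic DTI-ALPS Analysis with One-Carbon-Metabolism Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the link between one-carbon-metabolism
    biomarkers (serum folate, vitamin B12, homocysteine), glymphatic
    function measured by the diffusion-tensor-imaging analysis along the
    perivascular space (DTI-ALPS) index, and domain-specific cognition in
    Alzheimer's disease cohorts. Provides a diffusion-weighted phantom
    generator with known ground-truth tensors, log-linear diffusion tensor
    fitting (OLS/WLS) with framewise-displacement motion quality control,
    spherical-ROI ALPS index computation, control-referenced cognitive
    Z-scoring with domain composites, a synthetic cohort generator with
    configurable correlation structure, and the full statistical plan:
    normality-gated group comparisons, FDR-corrected (partial)
    correlations, folate-by-ALPS moderation regression, and median-split
    risk stratification.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
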