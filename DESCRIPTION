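Package: pulvtopo
Title: Pulvino-Cortical Functional Topography from Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Seed-based resting-state functional connectivity analysis of
    pulvino-cortical topography. Subdivides a thalamic seed nucleus into
    fixed-thickness slabs along anatomical axes (latero-medial,
    antero-posterior, ventro-dorsal), computes per-slab seed-to-cortex
    correlation maps with motion nuisance regression, Fisher r-to-z
    transformation and across-run one-sample t-tests, builds per-subject
    winner-take-all cortical assignment maps and group consensus maps,
    quantifies inter-subject consistency (Spearman spatial correlation,
    Friedman axis comparison with post-hoc Wilcoxon tests), and detects
    within-sulcus topographic gradients with polarity (direct versus
    reversed) by linear regression. Includes a synthetic multi-subject
    BOLD cohort generator with planted ground-truth gradients so every
    pipeline stage can be validated against a known answer.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
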