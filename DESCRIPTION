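Package: bolddelay
Title: BOLD Delay Mapping and Scan-Length Evaluation for Perfusion Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for assessing brain perfusion from resting-state fMRI via
    BOLD delay (hemodynamic lag) mapping. Implements preprocessing (confound
    regression, spatial smoothing, zero-phase band-pass filtering, framewise
    displacement and DVARS motion QC, scan-segment truncation), lagged
    cross-correlation delay mapping against a venous-sinus reference with a
    phase-randomized surrogate significance threshold, automated
    territory-constrained delineation of perfusion lesions on delay maps,
    spatial and volumetric agreement statistics (Dice, Bland-Altman, Cohen's
    kappa), and a synthetic 4D BOLD cohort generator with known ground-truth
    lag fields that drives an end-to-end scan-length experiment.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
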