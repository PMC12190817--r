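Package: megre
Title: Simulation and Precision Analysis for Mesoscopic Multi-Echo
    Gradient-Echo Brain MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end simulation and evaluation framework for
    high-resolution multi-echo gradient-echo (ME-GRE) brain MRI.
    Provides seeded digital brain phantoms with field-strength-specific
    tissue parameters and susceptibility-induced field maps, multi-channel
    receive-coil simulation with correlated noise, CAIPI-undersampled
    multi-echo k-space synthesis under rigid-body motion and B0 drift,
    navigator-based motion and field-change estimation, SENSE and
    iterative motion/B0-corrected reconstruction with analytic noise maps,
    R2* and frequency mapping, intrinsic-SNR estimation, Cramer-Rao
    precision bounds for R2*, frequency and susceptibility, and
    parallel-imaging g-factor evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
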