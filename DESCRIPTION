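Package: admmFPM
Title: ADMM Blind Phase Retrieval for Fourier Ptychographic Microscopy
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and reconstruction toolkit for Fourier ptychographic
    microscopy (FPM). Implements blind phase retrieval by the alternating
    direction method of multipliers (ADMM) with joint pupil-aberration
    recovery, alongside a sequential Gauss-Newton solver with self-adaptive
    step size and a momentum-accelerated ptychographic iterative engine
    (mPIE) for comparison. Includes an LED-array forward-model simulator
    with Gaussian and Poisson darkfield noise models, structural-similarity
    (SSIM) evaluation with ambiguity-aware alignment, dataset and
    reconstruction-bundle I/O, and experiment drivers for noise-robustness
    sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, grDevices, graphics, tiff, yaml, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
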