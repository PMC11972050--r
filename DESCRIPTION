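Package: tstperf
Title: Model-Based Dynamic CT Perfusion Reconstruction with the Time
    Separation Technique
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for model-based reconstruction of dynamic (CB)CT
    perfusion scans using the time separation technique: temporal basis
    sets (analytical trigonometric and prior-knowledge bases extracted by
    singular value decomposition), per-pixel projection-coefficient
    fitting, per-basis iterative tomographic reconstruction (CGLS),
    sweep-wise static reconstruction, and indicator-dilution perfusion
    maps (blood flow, blood volume, mean transit time, time to peak) by
    truncated-SVD deconvolution of the arterial input function. Includes
    a synthetic multi-sweep acquisition simulator (gamma-variate digital
    perfusion phantom, bidirectional view schedules, Poisson photon
    noise) and quantitative map evaluation (masked Pearson correlation,
    wavelet-based noise estimation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
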