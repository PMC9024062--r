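Package: octadc
Title: Automated Dispersion Compensation for Spectral-Domain OCT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: End-to-end pipeline for depth-dependent chromatic dispersion
    compensation in spectral-domain optical coherence tomography (SD-OCT).
    Simulates broadband-source interferograms over multilayer retina-like
    samples with depth-varying second-order dispersion, reconstructs B-scans
    with numeric spectral phase correction, discovers per-depth optimal
    compensation coefficients and stitches all-depth-compensated ground
    truths, trains a multichannel encoder-decoder restoration network on
    stacks of partially compensated B-scans, and evaluates restorations with
    PSNR, multi-scale structural similarity (MS-SSIM), differential intensity
    maps and axial point-spread-function analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
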