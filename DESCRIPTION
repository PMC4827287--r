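Package: chondroquant
Title: Mechanics, Bioreactor Strain and Histochemical Staining Analysis for
    Engineered Cartilage Constructs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis chain for tissue-engineered cartilage-like constructs
    cultured under force-controlled cyclic compression. Extracts construct
    thickness (tare-load detection) and tangent instantaneous moduli from
    cyclic unconfined-compression traces via an exponential stress-strain
    fit; estimates the strain applied by a force-controlled bioreactor
    whose plunger bears on the construct and a silicone limiter ring in
    parallel; quantifies Alcian blue in stained-section images by
    SVD-based automatic stain-vector estimation, least-squares colour
    deconvolution and whole-image Otsu thresholding within manually
    demarcated regions of interest; and relates staining metrics to
    log10 compressive modulus by ordinary least squares and rank-sum group
    comparisons. Includes seeded synthetic-data generators (mechanics
    traces, Beer-Lambert histology images, correlated cohorts, growth
    trajectories) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    minpack.lm,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
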