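Package: sharpgate
Title: Sharpness-Gated Mixture-of-Experts for Tile-Based Slide Classification Under Blur
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying and mitigating the impact of out-of-focus
    (blurred) regions on tile-based whole-slide-image classifiers. Implements
    Gaussian blur degradation, variance-of-Laplacian (LV) sharpness scoring
    and quality-control filtering, sigma-to-LV calibration, derivation of LV
    gating thresholds, blur-specialised expert models (a tile-level logistic
    classifier and a gated-attention multiple-instance head), and the
    mixture-of-experts inference rules that route tiles to experts by
    sharpness and combine expert outputs into slide-level predictions.
    Includes a seeded synthetic-cohort generator with class-dependent
    high-frequency texture and a benchmark harness with cross-blur
    sensitivity sweeps and mixed-blur scenario comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
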