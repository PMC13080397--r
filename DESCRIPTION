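Package: ecmtme
Title: Extracellular Matrix Structure Metrics and Tumor Microenvironment
    Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies extracellular-matrix (ECM) fiber architecture from
    stained-tissue images (skeleton-based fiber metrics, curvature,
    high-density matrix, gap analysis, gliding-box lacunarity, box-counting
    fractal dimension) and Haralick gray-level co-occurrence texture
    features with cross-experiment batch normalization; scores bulk
    expression cohorts with a composite anti-tumor-microenvironment
    (anti-TME) gene signature via single-sample enrichment; integrates the
    two into a per-sample structure index by correlation screening of the
    metric panel; ranks matrisome genes as candidate targets across two
    tumor models; and profiles immune and stromal cell infiltration in
    fixed-width distance bands from the tumor interface. Ships a synthetic
    data generator (fiber images, expression cohorts with planted effects,
    spatial point patterns) so every stage can be exercised against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    edgeR,
    fgsea,
    png,
    stats,
    tiff,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
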