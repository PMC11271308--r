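Package: hsdquant
Title: Quantification Pipeline for a High-Sugar-Diet Developmental Screen
    and Insulin-Signaling Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical and image-quantification operators for a
    Drosophila high-sugar-diet developmental-delay screen and its
    follow-up assays. Implements the time-to-50%-pupariation
    interpolation statistic, sugar-dependent excess-delay estimation and
    hit classification; background-corrected ROI and ratiometric
    fluorescence quantification, nucleus-to-nucleus line-profile
    membrane-enrichment scoring and lipid-droplet area fractions;
    TMT-style phosphoproteomic insulin-response filtering, counting,
    dependence-set and pathway-overrepresentation analysis; and
    standard-curve calibration with protein-normalized metabolite and
    ELISA quantification. Ships seeded synthetic-data generators with
    planted ground truth for every assay so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    withr,
    yaml,
    tiff,
    pracma,
    minpack.lm
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
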