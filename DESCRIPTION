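Package: gudpeck
Title: Giving-Up Densities for Every Species Visiting a Seed Tray
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates giving-up densities (GUDs) for every bird species
    visiting depletable seed trays from video-scored peck-event logs.
    Implements foraging-bout segmentation, minimum-individual density
    estimation from visit concurrency, the GUD-Peck linear model relating
    final tray GUD to cumulative pecks, forager density and species
    identity, per-species consumption rates, and yard-type community
    comparisons (MRPP with Bray-Curtis distance, Pielou evenness,
    ANOVA/ANCOVA, paired microhabitat and rank tests). Ships a mechanistic
    optimal-foraging simulator with known ground truth that emulates a
    20-yard, two-tray, 24-hour residential study design for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
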