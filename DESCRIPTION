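Package: brainage
Title: Brain Age Estimation from Gray-Matter Density Maps and
    Health-Marker Statistics
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates individual brain age from registered gray-matter
    density volumes using principal component reduction followed by
    relevance vector regression with a linear kernel, and derives the
    brain age gap (BrainAGE) score as estimated minus chronological age.
    Includes the downstream gender-stratified statistical analysis of
    BrainAGE against physiological and clinical chemistry markers
    (ANCOVA with gender interaction, partial least squares with VIP
    ranking, quartile contrasts with Holm correction, combined
    healthy/risky median-split groups) and a calibrated synthetic cohort
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
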