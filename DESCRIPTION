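Package: cbdscore
Title: Weighted-Rubric Labeling-Quality Scoring for Cannabis-Based Products
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the labeling quality of cannabidiol (CBD)-based drug products
    against a weighted 45-criterion rubric divided into four domains (prescription,
    good manufacturing practices, safety of use, laboratory testing), classifies
    total scores into three satisfaction bands, models the manufacturer e-mail
    follow-up protocol that can upgrade preliminary to final scores, and compares
    regulatory groups with median/IQR summaries and a tie-corrected Mann-Whitney
    U test (exact and normal-approximation modes). Includes a seeded synthetic-data
    generator that draws binary criterion-fulfillment vectors uniformly over the
    subset-sum solutions achieving a prescribed total score, and ships the published
    score table of 105 products marketed in Brazil as a machine-readable fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
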