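Package: sehgrb
Title: Dietary Selenium-Mercury Risk-Benefit Assessment for Young Children
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Risk-benefit assessment of dietary selenium against mercury
    exposure in young children. Scores foods by the Se:Hg molar ratio and the
    health benefit value of selenium (HBV_Se), estimates daily elemental
    intakes from food-frequency data (EDI, adequate-intake percentages, net
    selenium surplus, hazard quotients), derives safe consumption limits
    (CR_lim and monthly CR_mm under both exchange-serving and fish-meal
    conventions), computes weight- and height-for-age z-scores from LMS
    growth references, and fits covariate-screened multivariable regressions
    of growth outcomes on net selenium adequacy. A seed-deterministic
    synthetic-data module generates food panels, cohorts, intakes and growth
    outcomes with known ground truth so the whole pipeline is testable
    without access to cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
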