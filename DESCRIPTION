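Package: fertkin
Title: Kinetics of Fertilization and Polyspermy Blocks from
    Interval-Censored Chronograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the kinetics of mammalian fertilization and
    of the blocks to polyspermy from interval-censored single-oocyte
    observation data.  Provides a chronogram data model for per-spermatozoon
    penetration and fusion time windows, landmark-based refinement of fusion
    windows from sequential observation rounds, a uniform-within-window Monte
    Carlo estimator of cumulative event-count curves with bootstrap confidence
    bands, least-squares fits of exponential penetration-block and
    fusion-block models, a mechanistic Monte Carlo simulator of sperm
    penetration and fusion with switchable blocks, and a synthetic-data
    generator that reproduces the observation-censoring process for
    end-to-end parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    parallel,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
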