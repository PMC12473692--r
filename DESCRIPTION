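Package: twosexlt
Title: Age-Stage Two-Sex Life Tables and Entomopathogen Bioassay Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Demographic analysis of insect cohorts with the age-stage,
    two-sex life table framework of Chi and Liu: age-stage survival
    matrices, fecundity schedules, net reproductive rate, intrinsic and
    finite rates of increase from the Euler-Lotka equation, mean
    generation time, age-stage life expectancy and reproductive value,
    with bootstrap standard errors and paired bootstrap comparison of
    cohorts.  Companion virulence-bioassay statistics: Abbott-corrected
    mortality, three-parameter logistic time-mortality fits with LT50,
    probit dose-response fits with LC50 and Fieller confidence limits,
    endophytic colonization rates, and arcsine square-root ANOVA with
    Holm-corrected LSD letters.  Includes an individual-based synthetic
    cohort and bioassay generator for testing the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
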