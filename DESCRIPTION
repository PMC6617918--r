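Package: gasrisk
Title: Altitude-Travel Expansion Risk for Intravitreous Gas Tamponades
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the volume of an intravitreous gas or air tamponade
    from the patient-perceived fluid/gas interface height in an
    oblate-spheroid vitreous cavity, predicts its expansion under Boyle's
    law when travelling to a higher altitude using the International
    Standard Atmosphere pressure model, and reports an
    intraocular-pressure-elevation risk category from the ratio of the
    volume increase to the anterior-chamber volume. Also provides the
    accompanying interobserver agreement toolkit (Bland-Altman bias and
    limits of agreement, exact and approximate Wilcoxon matched-pairs
    signed-rank tests, Likert tabulation), cohort CSV input/output with
    validation, a synthetic-cohort generator for testing and calibration
    studies, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
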