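Package: serpintools
Title: Progress-Curve Kinetics and Biochemical Profiling of Serpin
    Protease Inhibitors
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for the biochemical characterization of
    serpin-class irreversible ("suicide substrate") protease inhibitors.
    Fits pseudo-first-order progress curves to obtain kobs, regresses
    kobs against inhibitor concentration to obtain the apparent
    second-order constant, and applies the substrate-competition
    correction (1 + [S]/Km) to report the true association rate
    constant ka. Also estimates the stoichiometry of inhibition as the
    x-intercept of fractional-activity titrations, first-order thermal
    and pH inactivation half-lives with censored (">t_max") reporting,
    protease-panel and fecal-protease inhibition summaries, pairwise
    global alignment with percent identity, Schechter-Berger P-position
    labeling, and mass-based reactive-center-loop cleavage-site mapping.
    A synthetic-data generator emulates every assay so the whole
    pipeline is testable by parameter recovery without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
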