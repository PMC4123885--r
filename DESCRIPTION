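Package: dietguild
Title: Dietary Guild Inference from Dental Microwear, Shearing Crests,
    and Body Mass
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for assigning mammals to one of five feeding guilds
    (grazer, browser, hard-object feeder, insectivore, carnivore) from
    three independent lines of dental evidence: low-magnification
    microwear feature counts (fine/coarse scratches, small/large pits per
    0.04 mm2 field), the Shearing Crest Score (summed shearing-crest
    length standardised by the square root of molar crown area), and
    species body mass.  Provides the univariate statistics used in
    comparative microwear work (log-transformed counts, one-way and
    nested ANOVA, Fisher LSD post-hoc tests), a from-scratch canonical
    linear discriminant analysis with Wilks' Lambda, Bartlett's
    chi-square approximation, structure coefficients and leave-one-out
    classification, and a hierarchical body-mass / SCS / microwear
    decision workflow with decision traces.  A guild-structured
    specimen simulator makes every stage of the pipeline testable
    without museum material.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
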