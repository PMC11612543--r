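Package: minharmonic
Title: Two-Sex Population Projection Models with the Minharmonic Mating
    Function
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mating (pair-formation) functions for discrete-time two-sex
    population projection models, centred on the minharmonic mating
    function: a one-parameter blend of the minimum and harmonic-mean
    functions whose parameter e fixes the mating efficiency at the
    balanced operational sex ratio while never forming more unions than
    the limiting sex allows.  Includes extensions to polygynous and
    polyandrous mating systems via the harem size, a grid-based checker
    for the mandatory and desirable validity properties of mating
    functions, a nonlinear size-structured two-sex matrix projection
    engine, and scenario drivers for harvest analyses of a wild boar
    (Sus scrofa) population, including growth-rate estimation at a
    target equilibrium operational sex ratio.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
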