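Package: iodamage
Title: Strand-Break Modelling for DNA-Incorporated Iodine-125 Decays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the spatial distribution of DNA strand breaks produced by the
    Auger-electron cascade of an iodine-125 atom incorporated into a short DNA
    duplex. Provides a calibrated synthetic generator for per-decay scored
    energy-deposition and OH-radical events, direct (energy-threshold and
    probabilistic-window) and indirect (per-hit probability) strand-break calling,
    single- and double-strand-break yields, end-labelled fragment-size
    distributions with their analytic forward model, the iterative
    fragment-to-break-probability correction and a demonstration of its
    normalisation degeneracy, and grid-search fits of the break energy threshold
    and OH interaction probability against observed fragment fractions via a
    log-scale sum-of-squares objective. Includes a Charlton-style helical DNA
    geometry classifier for raw-position scored data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
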