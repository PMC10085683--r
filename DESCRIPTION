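Package: chromonema
Title: Helical Coiling Analysis and Polymer Modelling of Metaphase Chromatids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring and modelling the helical coiling of mitotic
    chromatids from chromosome conformation capture (Hi-C) data. Computes
    contact-probability decay curves P(s) on logarithmic distance bins, their
    log-log derivatives and metaphase/interphase ratio tracks; estimates the
    helical turn length along chromosomes by fitting an exponential-plus-
    Gaussian model to regional contact-distance histograms; builds the
    variable-radius helical path implied by a turn-length profile and derives
    turn counts, physical chromosome length and chromatin density; classifies
    sister-chromatid-exchange segment geometry against the chromonema model;
    and simulates bottle-brush chromatin polymers (nested major/minor loops
    tethered to a helical or half-helical axis) with Langevin dynamics,
    reading contact probabilities back out of simulated conformations.
    Includes synthetic-data generators with known ground truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
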