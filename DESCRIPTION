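Package: yeastnuc
Title: Restraint-Based Polymer Models of the Budding-Yeast Nucleus and
    Position-Expression Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained bead-and-spring polymer simulation of the
    Saccharomyces cerevisiae interphase nucleus under nuclear-landmark
    restraints (spindle pole body, nucleolus, nuclear envelope), for
    wild-type and fusion-chromosome karyotypes. Computes ensemble-level
    structural statistics (equal-volume radial shell occupancy, in-silico
    contact maps, 2D localization densities, locus displacement from the
    nuclear envelope and spindle pole body) and the downstream
    expression-versus-nuclear-position analyses (baseline construction,
    fold changes, LOESS and binned-group trends, sequential ANOVA,
    windowed r-squared comparisons), together with a synthetic
    expression-data generator for calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    generics,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
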