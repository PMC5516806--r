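Package: tandemtox
Title: Kinome Occupancy Profiling and Tandem Kinetic Pathway Models for
    Kinase-Inhibitor Toxicology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the in-silico arm of kinase-inhibitor systems
    toxicology. Computes kinase occupancy profiles from dissociation
    constants and unbound plasma exposures, shortlists differential
    off-target candidates between drugs that share primary targets, and
    fits IC50 values from in-vitro inhibition assays. Provides three
    compact kinetic models - the glycogen-phosphorylase regulatory
    cascade with competitive phosphorylase-kinase inhibition, the
    oxidative pentose-phosphate pathway, and glutathione redox cycling
    with an optional vitamin-E hydrogen-peroxide quenching node - and a
    tandem coupler that chains them through fold-changes of interface
    metabolites to predict drug-induced glycogen accumulation, NADPH
    depletion, glutathione loss, and antioxidant rescue. Includes
    seedable synthetic-data generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    scales,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
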