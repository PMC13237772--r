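Package: hdxkd
Title: Apparent Dissociation Constants from HDX-MS and HDX-MS/MS Titrations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for determining apparent dissociation constants (KDapp) of
    small-molecule-protein interactions from hydrogen-deuterium exchange mass
    spectrometry (HDX-MS) titration experiments. Computes differential
    deuterium uptake between apo and liganded states, applies a hybrid
    significance criterion, fits protection versus ligand concentration to a
    single-site Langmuir isotherm at peptide and single-residue resolution,
    resolves residue-level deuteration from ECD c/z fragment-ion ladders with
    hydrogen-scrambling quality control, and includes a forward simulator of
    EX2 exchange under ligand occupancy for validation at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
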