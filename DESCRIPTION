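Package: pdregio
Title: Regioselectivity and Mechanism Prediction for Pd-Catalysed Aromatic
    C-H Activation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rationalises Pd(II)/acetate-catalysed aromatic C-H activation by
    enumerating symmetry-unique aromatic C-H sites of a substrate, building
    candidate palladium acetate intermediates for the proton-abstraction (CMD)
    and electrophilic aromatic substitution (SEAr) mechanisms, screening them
    by energy and Pd-C geometry, classifying the operative mechanism with a
    thresholded ipso-complex stability parameter, and predicting site
    selectivity and product ratios by Boltzmann weighting of relative Gibbs
    energies. Includes an NWChem-dialect input-deck writer and output-log
    parser with an automated failure-remediation state machine, interchangeable
    energy backends (tabulated and synthetic) for desk-scale runs, and the
    published validation tables as machine-readable fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
SystemRequirements: OpenBabel (obabel, obenergy) for structure parsing and
    3D conformer generation
Config/testthat/edition: 3
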