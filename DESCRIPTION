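Package: varitrait
Title: Multi-Trait Biophysical Characterization and Scoring of Protein Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the biophysical consequences of missense
    variants on a multifunctional flavoprotein (NQO1) across several assay
    types: fluorescence cofactor-binding titrations fitted with the quadratic
    tight-binding isotherm, limited-proteolysis kinetics converted to local
    stability changes, thermal denaturation scans normalized with linear
    baselines, and isothermal titration calorimetry decomposed into intrinsic
    and conformational binding energetics. Trait measurements are encoded into
    a semiquantitative pathogenicity rubric, combined into experimental scores,
    and correlated with consensus bioinformatic predictor scores. A synthetic
    data module generates assay datasets with known ground truth so the whole
    pipeline is testable end to end.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
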