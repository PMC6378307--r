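Package: zcmeta
Title: Carbon Oxidation State of Metagenomic Sequences Along Redox Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the average oxidation state of carbon (Z_C) of DNA, RNA
    and protein pools from metagenomic sequence files, with subsampling-based
    uncertainty estimates, per-taxon pools, and a thermodynamic model of the
    relative chemical affinity of biomacromolecule synthesis as a function of
    redox potential (Eh). Includes a synthetic-metagenome generator that
    produces multi-sample redox gradients with known ground truth, so the
    whole pipeline is testable without external data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
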