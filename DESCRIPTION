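Package: pccleave
Title: Mapping Proteolytic Cleavage in Membrane Protein Complexes from
    Gel-Slice Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Locates and quantifies proteolytic cleavage events in large
    membrane proteins from GeLC-MS/MS peptide intensity data.  Peptide ion
    currents recorded per gel slice are mapped onto protein open reading
    frames to detect cleavage by change-points in the slice distribution of
    peptides, to quantify fragment stoichiometry by region intensity ratios,
    and to verify cleavage products by in-silico tryptic digestion, peptide
    m/z arithmetic and glycan-corrected fragment masses.  Ships a synthetic
    data generator emulating a two-cohort (PKD1-mutant versus normal) urinary
    exosome-like vesicle peptide dataset so the whole pipeline can be
    exercised without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
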