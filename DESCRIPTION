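Package: topdownptm
Title: Top-Down Mass Spectrometry Proteoform Identification, PTM
    Localization and Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for characterizing intact-protein proteoforms from
    high-resolution (FTICR) mass spectra: exact elemental compositions and
    aggregated isotopologue distributions, intact-mass matching of candidate
    post-translational modification (PTM) compositions at ppm tolerance,
    electron capture dissociation (ECD) c/z-ion fragment-ladder generation
    and breakpoint-based PTM site localization, and relative quantification
    of proteoform classes by isotopic-envelope integration across charge
    states. Includes a seeded simulator of FTICR MS1 and ECD MS/MS spectra
    so that every stage is testable without instrument data. The worked
    reference system is yeast histone H2B and its dimethylation at lysine 37.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
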