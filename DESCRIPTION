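Package: evlptiter
Title: Titration and Transduction Analysis for Engineered Virus-Like Particles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification and analysis toolkit for base-editor engineered
    virus-like particle (BE-eVLP) preparations. Implements absolute sgRNA
    copy-number quantification from qPCR standard curves with replicate
    quality control, batch standardization by dose adjustment against a
    reference preparation, split NanoBiT (HiBiT/LgBiT) luciferase titration
    and live-cell transduction-kinetics analysis, and a HiBiT-like peptide
    motif scan over six-frame translations of plasmid sequences with exact,
    Hamming, and biochemical-property matching, plus in-silico PCR amplicon
    prediction. A synthetic-data module generates qPCR plates, luminescence
    time courses, and motif-bearing sequences with known ground truth so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
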