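Package: mirhomology
Title: Homology-Based MicroRNA Discovery, Hairpin Filtering, Target
    Prediction and Comparative-Ct Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis toolkit for conserved microRNA characterization in
    newly sequenced genomes. Maps reference mature miRNAs onto a genome by
    exact matching on both strands, excises precursor windows, folds them
    with a deterministic dynamic-programming model, applies stem-loop
    filtering criteria built around the minimum folding free energy index
    (MFEI), predicts target sites under seed-region complementarity rules,
    and quantifies tissue-specific expression with the comparative-Ct
    (2^-ddCt) method. Ships a transcribed catalog of 101 sardine (Sardina
    pilchardus) miRNAs as its reference surface and a synthetic-data
    generator that produces genomes, transcripts and Ct tables with known
    ground truth for validating every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
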