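Package: entrapbench
Title: Entrapment-Based Auditing of False Discovery Rate Control in
    Tandem Mass Spectrometry Analysis
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for auditing the false discovery rate (FDR) control of
    proteomics and metabolomics search engines using entrapment
    experiments. Builds paired shuffled entrapment databases at the
    peptide and protein level (any entrapment-to-target ratio r) and
    foreign-species entrapment databases from FASTA input; computes the
    combined, lower-bound, sample and paired entrapment estimates of the
    false discovery proportion (FDP), together with the k-matched
    generalization of the paired estimator, FDP-versus-threshold curves,
    coverage bands and discovery-inflation rates; provides reference FDR
    control procedures (target-decoy competition, PSM-and-peptide double
    competition, and decoy-based empirical p-values with
    Benjamini-Hochberg or Storey adjustment); and ships a calibrated
    score simulator with known ground truth so the directional
    guarantees of the estimators can be checked by Monte Carlo.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, Software, StatisticalMethod
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
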