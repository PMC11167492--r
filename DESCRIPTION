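Package: StructMotif
Title: Structure-Based Prediction of Transcription Factor Binding Motifs
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Derives knowledge-based statistical potentials from amino
    acid to dinucleotide contacts in transcription factor (TF) - DNA
    complex structures, optionally extended with protein-binding
    microarray (PBM) 8-mer data, and uses them to predict a TF's
    position weight matrix (PWM) directly from structure. Includes an
    annotated-complex parser with secondary-structure and solvent
    accessibility assignment, a 48-class contact environment classifier,
    interval and cumulative distance-dependent potentials with
    polynomial smoothing and redundancy filtering, exact enumeration and
    dynamic-programming search over candidate binding sequences, MEME
    minimal format motif input/output, empirical-null motif comparison,
    rank-based evaluation (normalized ranking score, rank enrichment,
    nearest-neighbor baseline, 8-mer classification benchmark, per-family
    grid search), exact p-value PWM scanning with a binned majority-vote
    binding-site caller, and a synthetic fixture generator so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
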