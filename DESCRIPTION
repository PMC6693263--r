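Package: venomscan
Title: Venom-Gland Transcriptome Annotation and Novel-Toxin Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Annotates assembled venom-gland (telson) transcriptomes against a
    labeled arthropod protein database, using a control-tissue (chela)
    transcriptome to subtract shared physiological transcripts. Implements
    coverage normalization, orthologue subtraction, six-frame ORF prediction,
    a self-contained Smith-Waterman local-alignment search engine with
    Karlin-Altschul E-values, similarity-based toxin-family labeling,
    coverage filtering and signal-peptide validation, plus a novel-toxin
    discovery procedure that clusters highly expressed unidentified
    transcripts by signal peptide and cysteine scaffold, expands clusters
    against pooled transcriptomes, and applies a rule-based novelty
    classifier. Ships a deterministic synthetic-data generator with
    machine-readable ground truth so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
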