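Package: scanact
Title: Nomination and Prioritization of Adoptive T-Cell Therapy Targets
    from Single-Cell Tumor Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scoring framework for discovering and prioritizing targets for
    engineered T-cell therapies (CAR-T, logic-gated CAR-T, TCR-T and
    peptide-centric CAR-T) from single-cell tumor expression data.  Provides
    malignant-cell classification from copy-number state matrices and
    bulk-similarity scores, aggregation of differential-expression calls,
    on-target off-tumor toxicity filters and the monospecific CAR
    targetability score, Boolean logic-gated ("AND", "AND-NOT") gene-pair
    scores, peptide-MHC targetability with population-weighted HLA allele
    frequencies, entropy-weighted peptide similarity and tissue-level
    cross-reactivity scoring, and Target Priority Indices that integrate
    multi-omic validation evidence.  External presentation and immunogenicity
    predictors are consumed as score tables; a synthetic-fixture generator
    emulates every input so the full pipeline runs without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
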