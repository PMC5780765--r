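Package: motifgrammar
Title: Cell-Type-Specific DNA Motif Grammar Discovery from TF Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers cell-type-specific combinations of transcription factor
    (TF) DNA motifs ("motif grammars") in ChIP-seq binding sites. Fixed-width
    windows around peak centres are annotated with occurrence counts of a
    position weight matrix (PWM) database via log-odds scanning of both
    strands; a multi-class random forest is trained on the count matrix to
    predict the cell type of origin; motif importance is quantified by scaled
    out-of-bag permutation importance; and compact conjunctive rules over
    motif counts are extracted from the forest, pruned, selected and filtered
    into an interpretable grammar. Includes a synthetic-data generator that
    plants class-specific motif grammars into background sequence so the whole
    pipeline can be validated without external downloads, plus repeated
    stratified cross-validation with one-vs-rest AUROC and F1 evaluation and a
    window-size sweep.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    ranger,
    Rcpp,
    jsonlite,
    methods,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
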