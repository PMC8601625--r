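Package: taxcurator
Title: Curation and Evaluation of Marker-Gene Reference Sequence Databases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building, curating and evaluating reference sequence
    taxonomy databases for marker-gene (amplicon) classification. Parses
    SILVA-style (taxrank/taxmap/Newick taxtree) and NCBI taxdump-style
    taxonomy sources into rank-standardized lineages with optional rank
    propagation; filters sequences on homopolymer runs, ambiguous bases,
    length and annotation depth; dereplicates and greedily clusters sequences
    with last-common-ancestor, majority or super-majority consensus taxonomy;
    computes database information metrics (unique labels, Shannon entropy,
    unclassified and terminal label counts, kmer entropy, cross-database
    label overlap); and estimates taxonomic classification accuracy with a
    kmer naive Bayes classifier under best-case (fit on the full database)
    and stratified k-fold cross-validated evaluation regimes, scored as
    per-rank precision, recall and F-measure. A seeded synthetic-database
    generator emulates all supported input formats for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    jsonlite,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
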