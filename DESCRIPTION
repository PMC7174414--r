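Package: oricsvm
Title: Identification and Taxonomic Classification of Bacterial
    Replication Origins with Gapped k-mer SVMs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Identifies bacterial replication-origin (oriC) sequences in
    chromosomes or chromosomal fragments.  Candidate windows are anchored
    on seed 9-mers extracted from known origins, scored with a gapped
    k-mer (or spectrum) string-kernel support vector machine, and labelled
    with an abstaining two-cutoff decision rule on per-sequence
    min-max-normalized decision values.  Also provides primitives of the
    semi-automated ground-truth curation procedure (cumulative GC-skew,
    intergenic windows, DnaA-box scanning, seed-matched negatives),
    one-vs-rest taxonomic classifiers with macro-averaged AUPR
    evaluation, motif-importance extraction with overlap assembly into
    IUPAC consensus motifs, and a synthetic-data generator that plants
    oriC grammar (DnaA boxes, DnaA trios, AT-rich unwinding elements)
    into seed-matched fragments and GC-skewed circular chromosomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    kernlab,
    methods,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    GenomicRanges,
    optparse,
    pROC,
    randomForest,
    rtracklayer,
    S4Vectors,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
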