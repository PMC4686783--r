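Package: promstruct
Title: Structural-Property Encoding and Classifier Evaluation for Promoter Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how DNA sequence length and training-set size
    affect promoter prediction from physicochemical structural profiles.
    Encodes nucleotide windows around transcription start sites into
    concatenated di- and trinucleotide structural-property profiles, builds
    balanced promoter/non-promoter datasets from genome sequence and TSS/gene
    annotation (with exclusion-distance sampling of negatives), generates
    seeded synthetic genomes and labelled sequence sets with a controllable
    class signal, evaluates SVM, Random Forest and k-NN classifiers under
    shared-partition stratified cross-validation (F-measure, Cohen's kappa),
    and compares matched per-fold scores with the Friedman test and the
    Nemenyi post-hoc procedure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    kernlab,
    randomForest,
    class,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
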