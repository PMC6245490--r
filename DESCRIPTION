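Package: swscan
Title: Sliding-Window Motif Scoring for Calmodulin-Binding Protein
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scores protein sequences against short linear motifs (SLiMs)
    with a sliding-window method in two flavours: probability-matrix
    scoring of MEME-style position-specific probability matrices (SWS_PPM)
    and reciprocal-class-size scoring of regular-expression motifs
    (SWS_RE). Per-protein total (S) and averaged (T) motif scores are
    assembled into feature matrices for classifying motif-binding versus
    non-binding proteins with k-NN, SVM, random forest and naive Bayes,
    with chi-square ranking, wrapper and recursive backward-elimination
    feature selection. Bundles the 14 canonical calmodulin-binding motif
    patterns and a planted-motif synthetic sequence generator for
    end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    class,
    e1071,
    jsonlite,
    kernlab,
    methods,
    optparse,
    pROC,
    randomForest,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
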