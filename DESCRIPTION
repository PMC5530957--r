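Package: bpac
Title: Transcription Factor Binding Site Prediction from Chromatin
    Accessibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Supervised prediction of bound transcription factor (TF)
    binding sites from chromatin accessibility data (DNase-Seq or
    ATAC-Seq).  Candidate sites are found by scanning a genome with a
    log-odds position weight matrix at an exact p-value cutoff; each
    candidate is described by static sequence features (PWM score,
    evolutionary conservation, distance to the nearest TSS) and dynamic
    accessibility features (per-base read and cut profiles at the site
    and its flanks, and footprint scores), and a random-forest
    classifier is trained against ChIP-Seq peak labels.  The package
    quantifies how well such models transfer across TFs and cell types
    (self, cross-TF, multi-TF, cross-cell and mixed prediction), and
    ships a synthetic-data generator with known ground truth covering
    the observed footprint morphologies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    randomForest,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
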