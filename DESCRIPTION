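Package: oriscan
Title: Dissection and Prediction of Fission Yeast DNA Replication Origins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to dissect the DNA-encoded architecture of fission yeast
    replication origins from ChIP-seq fold-enrichment tracks, genome sequence
    and annotation. Implements peak post-processing and Orc/Mcm co-localization
    (OM/O site) classification, poly(dA) motif scanning with exact p-values and
    FDR control, AT-content and nearest-neighbour DNA melting-energy profiles,
    transcription-poor span measurement, intergenic-region derivation with
    gene-orientation classes, RBF-kernel support vector machine origin
    prediction with repeated stratified cross-validation (ROC/PR AUC, F-score
    feature ranking), Monte Carlo and bootstrap null models, and a synthetic
    genome generator with planted origins for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    Biostrings,
    rtracklayer,
    kernlab,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
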