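Package: operotext
Title: Operon Prediction from Textual Serialization of Gene-Pair Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts bacterial operons by reframing gene-pair classification as
    text classification. Adjacent gene pairs are described by sequence-derived and
    annotation-based features (gene lengths, intergenic distance, strand orientation,
    GC content difference, functional annotations, protein families, and adjacency
    conservation across a genome panel), serialized into deterministic natural-language
    paragraphs, and classified as operonic or non-operonic. Includes dataset
    construction from operon annotation tables, leave-one-species-out and mixed-split
    evaluation, feature ablation and inference-time resilience protocols, operon
    assembly from pairwise calls, and a synthetic genome-panel generator for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    S4Vectors,
    GenomicRanges,
    BiocGenerics,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
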