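Package: periodx
Title: Periodontitis Stage and Grade Classification from Dental Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-track clinical-decision-support pipeline for classifying
    periodontitis stage (I-IV) and grade (A-C) from electronic dental
    records. One track extracts structured variables from free-text
    clinical notes with a configurable pattern schema and classifies them
    with a small feed-forward network; the other classifies the raw note
    text directly by windowing it into fixed-length token blocks, embedding
    each block with a pluggable transformer encoder, aggregating block
    embeddings with a recurrent layer, and applying a softmax head trained
    with balanced class weights and early stopping. Ships a synthetic
    periodontal-record generator (charts, histories, templated notes, and a
    staging/grading rule engine) so the full pipeline runs and is tested
    without any patient data, plus per-class precision/recall/F1 reports,
    confusion matrices, model-comparison tables, and a local-surrogate
    token-importance explainer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glue,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
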