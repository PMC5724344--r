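Package: ctsearch
Title: Content-Based Text and Image Retrieval for Head CT Study Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale content-based retrieval engine for corpora of head
    computed-tomography studies. Images are represented as bags of visual
    words (dense gradient-orientation patch descriptors quantized against a
    k-means vocabulary) and report text as stemmed, negation-filtered term
    bags; both modalities share one inverted index supporting text, image,
    combined and filtered search with study-grouped, capped result pages.
    Includes a retrieval evaluation harness (precision at k, study-level
    precision, at-least-one-relevant rate, SUS and USE questionnaire
    scoring), a reproducible synthetic head-phantom study generator with
    DICOM output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
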