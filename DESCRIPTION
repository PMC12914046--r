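Package: atlasdx
Title: Knowledge-Enhanced Retrieval-Augmented Classification for
    Histopathology Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Differential diagnosis of melanocytic neoplasm image patches by
    retrieval from a curated multimodal vector atlas. Class-specific
    multi-head attention experts retrieve reference image and knowledge-text
    embeddings, transformer fusion blocks refine them, and dual (local and
    global) temperature-scaled contrastive losses align the enhanced image
    and knowledge representations over a frozen encoder. Includes a
    three-tier taxonomy with partial-credit hierarchical scoring, an
    attention-based multiple-instance-learning stage for whole-slide bags,
    few-shot and supervised slide protocols, evaluation statistics
    (bootstrap confidence intervals, paired t-tests, majority-class
    baselines), and seeded synthetic generators for taxonomies, atlases,
    queries and slide bags.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    knitr,
    rmarkdown,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
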