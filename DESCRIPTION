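Package: salttol
Title: Composite Salt-Tolerance Evaluation and Multi-Omics Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comprehensive evaluation of plant stress tolerance from
    treatment-by-indicator physiological panels: control-relative indicator
    standardization with positive/negative polarity, principal-component
    analysis with variance-contribution weighting, membership (min-max)
    normalization of component scores, and weighted composite scoring and
    ranking. Also provides threshold screens for differentially expressed
    genes and differentially accumulated metabolites, nine-quadrant
    transcript-metabolite co-regulation classification gated on Spearman
    correlation, and synthetic-data generators that emulate the
    treatment-structured panels and paired omics matrices the pipeline
    expects, so every stage is testable without external data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
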