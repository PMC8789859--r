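Package: recurrevol
Title: Clonal Evolution Analysis of Paired Primary and Early-Recurrent Liver Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies hepatocellular carcinoma early recurrence as ancestral
    (clonally related to the primary tumor) or de novo (an independent second
    primary) from paired whole-genome somatic mutation tables, and reconstructs
    the evolutionary trajectory of each case. Implements mutation-set
    harmonization across a patient's samples (high-confidence filtering,
    copy-number-loss exclusion, force calling), a clonality index with a
    resampling-calibrated cutoff, cancer cell fraction estimation and
    multi-sample binomial mixture clustering, subclonal architecture
    reconstruction under pigeonhole constraints, driver timing, spatial and
    temporal heterogeneity metrics, and mutational signature refitting by
    evolutionary stage. Ships a synthetic cohort generator with known ground
    truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    ape,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
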