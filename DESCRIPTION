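Package: boolerank
Title: Boolean-Framework Gene Prioritization for Tumor Expression Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Integrative gene prioritization in a Boolean logic framework.
    Binary functional attributes (methylation, secreted protein, protein
    kinase, tissue specificity, post-translational modification,
    transcription factor, interactome hub) are weighted by phi-correlation
    against a cancer-gene reference, each gene's attribute pattern is
    decomposed into its Boolean roots and scored, and shortlisted genes are
    carried through rank-product differential expression, high-confidence
    interactome filtering, co-expression network centrality analysis, and
    clinical characterization (signature scoring, Kaplan-Meier survival
    stratification with log-rank tests). A synthetic-data module generates
    two-class expression, binary attribute tables, interaction evidence and
    survival records with controlled structure so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    generics,
    ggplot2,
    igraph,
    survival,
    stats,
    utils,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
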