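Package: dcnet
Title: Differential Co-Expression Network Analysis on Scored Protein
    Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds disease-related co-expression networks from two-condition
    expression matrices and a scored protein-protein interaction (PPI)
    network.  Calls differentially expressed genes with an empirical-Bayes
    moderated t-statistic (or Welch t), extracts the wild-type
    disease-related network (WDRN) of high-confidence PPI edges touching a
    differential gene, detects differentially correlated gene pairs by
    condition-specific Spearman significance with exact permutation
    p-values at small sample sizes, assembles the resulting differential
    network, finds dense modules with an MCODE-style algorithm, selects hub
    genes, and compares networks across tissues.  Includes a synthetic-data
    generator with planted signal so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
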