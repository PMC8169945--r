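Package: hspnet
Title: Protein Interaction Network Stratification for Disease Gene Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds evidence-scored protein-protein interaction networks
    around disease-associated seed genes, extracts the core network of
    inter-interactome hubs, runs multi-tool over-representation analysis
    with semantic-block merging, performs permutation-based keyword
    enrichment over enriched term names, and stratifies clinical-feature
    subnetworks by variance-scaled principal component analysis and
    hierarchical clustering with silhouette and multiscale-bootstrap
    (approximately unbiased) branch support. Ships a synthetic-fixture
    generator with plantable two-cluster functional structure so the whole
    pipeline is testable without a database download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    igraph,
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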