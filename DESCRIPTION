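Package: cipnnet
Title: Seed-Based Gene Network Growth and Scoring for Chemotherapy-Induced
    Peripheral Neuropathy
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Grows gene-interaction networks from literature-derived focus
    genes over a typed molecular-interaction knowledge base, following the
    seed-network paradigm of pathway-analysis tools: focus genes are ranked
    by triangular connectivity, seed networks are grown one hop at a time,
    merged through bridging non-focus genes and expanded greedily by
    specific connectivity (neighborhood Jaccard overlap) up to a size cap.
    Networks are scored with an exact right-tailed hypergeometric
    over-representation test (score = -log10 p). Includes a reproducible
    synthetic knowledge-base simulator (preferential-attachment scaffold
    with planted dense modules and ground truth), packaged curation tables
    for chemotherapy-induced peripheral neuropathy (study records, agent by
    gene evidence matrix, focus-gene sets, hub tables), hub detection at a
    connection-count threshold and log-log power-law degree diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
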