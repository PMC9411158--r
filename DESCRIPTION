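Package: comoa
Title: Disease Comorbidity Prediction from Shared Drug Mode-of-Action Proteins
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers per-disease mode-of-action (MOA) protein profiles from a
    probe-drug indication score matrix and a drug-to-protein target map,
    scores every disease pair for predicted comorbidity by the Jaccard
    overlap of their MOA protein sets with one-sided hypergeometric
    significance and Storey q-value FDR control, ranks
    comorbidity-enriched proteins and over-represented pathways, and
    benchmarks predicted comorbidity against clinical co-occurrence counts
    (log relative risk and phi score) including permutation null models and
    disease-disease network characterisation. Ships a seeded synthetic-world
    generator with planted disease modules so the whole pipeline is testable
    without external data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'comoa-package.R'
    'AllClasses.R'
    'benchmark.R'
    'cli.R'
    'comorbidity.R'
    'config.R'
    'enrichment.R'
    'io.R'
    'moa.R'
    'network.R'
    'stats.R'
    'synthetic.R'
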