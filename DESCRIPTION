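Package: rcifh
Title: Network-Weighted Scoring of miRNA Contributions to Impaired Fracture Healing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks differentially expressed microRNAs by their contribution to
    impaired bone fracture healing in aged versus adult cohorts. Each miRNA's
    fold-change difference between cohorts is weighted by its "network power":
    the summed degree, in an experimentally supported protein-protein
    interaction network, of its target genes surviving an evidence filter and
    an anticorrelated-expression filter. Includes differential-expression
    screening for miRNA arrays, miRNA-target interaction filtering, PPI graph
    construction, Fisher's exact over-representation analysis against GMT gene
    sets, a seeded synthetic-study generator with known ground truth, and a
    pipeline runner with a reproducible run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    igraph,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
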