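Package: metamod
Title: Integrated Metabolic Network Modules from Time-Course Metabolite
    Profiles and Transcript Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds metabolite reaction networks from KEGG KGML pathway
    files, scores network nodes from rank-based trend tests
    (Jonckheere-Terpstra and Mack-Wolfe umbrella tests) on time-course
    metabolite profiles via a beta-uniform mixture model of p-values, scores
    edges from enzyme presence and differential EST counts, and extracts
    maximum-scoring connected functional modules with an exact
    branch-and-bound solver in a two-step enrichment/module pipeline.
    Includes synthetic-data generators emulating dehydration/rehydration
    time-course experiments for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    optparse,
    stats,
    utils,
    vegan,
    withr,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
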