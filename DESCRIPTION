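Package: miRmRNet
Title: Integrative miRNA-mRNA Anti-Correlation Network Analysis of Treatment Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative analysis of paired microRNA and mRNA expression
    profiles measuring a cellular treatment response. Provides moderated
    two-group differential expression with Benjamini-Hochberg control,
    unsupervised sample clustering with Fisher's exact cluster-label
    association, construction of bipartite miRNA-mRNA anti-correlation
    networks with a permutation-based network-level false discovery rate
    and validated-interaction filtering, cross-culture network combination,
    hypergeometric pathway over-representation analysis, 2^-ddCt relative
    quantification of qPCR data, and a seeded synthetic-data generator with
    planted ground truth for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
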