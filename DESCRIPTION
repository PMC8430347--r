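Package: longnet
Title: Cross-Species and Inter-Tissue Network Analysis of Longevity Gene Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrative network analysis of aging- and
    longevity-associated gene panels: multi-source evidence integration with
    convergent-evidence scoring, 1:1 cross-species ortholog mapping with
    conserved-ortholog scoring and Venn partitioning, construction of
    species-specific physical protein-protein interaction subnetworks with
    exact degree/betweenness/closeness topology and hub ranking, discrete
    maximum-likelihood power-law fitting of degree distributions,
    hypergeometric over-representation analysis with Bonferroni correction
    and cross-context pathway intersection, pathway rewiring comparison via
    ortholog-translated edge Jaccard, expression-filtered tissue-specific
    subnetworks with conserved edge-module extraction and permutation-based
    expression/topology association, and confidence-filtered drug-target
    conservation mapping. Includes a parametric synthetic-study generator
    that emulates the statistical structure of the curated inputs (sparse
    multi-source membership, preferential-attachment interactomes, nested
    ortholog retention, planted enriched gene sets, planted tissue-conserved
    edge modules, mixed-confidence drug-target tables) so the full pipeline
    is testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
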