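Package: brainsig
Title: Anatomic and Cell-Type Transcriptomic Signatures of Brain Diseases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compares brain diseases through the regional and cellular
    expression of their risk genes. Builds z-scored anatomic expression
    profiles of disease gene sets over a brain-structure ontology, clusters
    them into anatomic disease groups (Ward linkage on one minus Pearson
    correlation), and quantifies cross-subject identifiability of disease
    signatures. Computes differential stability of regional expression,
    maps genes and diseases onto canonical co-expression module eigengenes
    via Fisher z-averaged correlations, and profiles diseases over
    single-nucleus cell types: tau expression specificity,
    expression-weighted cell-type enrichment by permutation test, cosine
    covariation interaction maps, consensus representations, and
    cross-species comparison through homologous cell types. A seeded
    synthetic-data generator emulates the statistical structure of the
    inputs (per-subject structure-by-gene matrices with planted modules,
    cell-type marker matrices with a specificity gradient, gene-disease
    association tables with evidence counts), so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, tools, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
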