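Package: lipidont
Title: Lipid Ontology Construction and Ontology Enrichment Analysis for
    Lipidomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds a lipid ontology that links tens of thousands of
    enumerated lipid species to classification, chemical, biophysical,
    functional and sub-cellular terms; parses heterogeneous lipid
    shorthand nomenclature into canonical species names; predicts
    membrane biophysical properties (chain-melting transition
    temperature, bilayer thickness, lateral diffusion) by multiple
    linear regression with quintile-based categorization against a
    reference lipidome; and performs ontology enrichment analysis on
    lipidomic datasets in a target-list mode (one-tailed Fisher exact
    tests) and a ranking mode (local statistics followed by one-tailed
    Kolmogorov-Smirnov tests), with Benjamini-Hochberg correction,
    term-subset restriction and redundant-parent pruning. Includes
    dataset preprocessing (fraction-of-total normalization, half-minimum
    imputation, z-scoring, complete-linkage clustering) and a synthetic
    fixture generator with planted enrichments for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
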