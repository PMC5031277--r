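Package: ontobalance
Title: Balanced Module Extraction from Large Biomedical Terminologies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Extracts "balanced" modules from large biomedical terminologies
    such as SNOMED CT: subsets whose classes keep their original paths to the
    root and their full axiomatic definitions, and whose per-sub-hierarchy
    class distribution approximates the source ontology's. Provides a
    signature-driven graph-traversal extractor (upward hierarchical closure
    plus definition-reference closure), stratified signature sampling by
    largest-remainder apportionment, and an iterative rebalancing algorithm
    that multiplicatively adjusts signature weights until the residual sum of
    squares of per-sub-hierarchy errors falls below a threshold. Includes a
    loader for a native JSON graph format and an OWL functional-syntax
    EL-like subset, sub-hierarchy shape profiling, squarified treemap layout,
    and a generator for synthetic SNOMED-like ontologies so that everything is
    testable without license-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    tools,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
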