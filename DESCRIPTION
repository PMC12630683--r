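Package: boolpath
Title: Signed Path Counting in the Stable States of Boolean Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies how strongly a Boolean network drives each node to
    its stable-state value by exhaustively counting the logically valid
    activatory and repressive paths that explain it. Reads and writes
    models in BoolNet (.bnet) format, computes minimal disjunctive normal
    forms of each rule and its negation (Quine-McCluskey prime implicants
    with exact cover selection), enumerates fixed points, extracts and
    simplifies stable-state-specific driver clauses, and counts signed
    acyclic expansion paths from any target back to the input nodes. Also
    provides an in-silico perturbation framework (additive and non-additive
    activation and inhibition via dedicated perturbation input nodes), a
    random-model generator stratified by size and maximum in-degree with a
    scalability harness, and phenotype scoring utilities (min-max scaling
    against a reference condition, Pearson correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    stats
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
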