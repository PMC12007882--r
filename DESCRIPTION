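Package: seedkit
Title: Seed Metabolite Inference in Genome-Scale Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers subset-minimal (or cardinality-minimal) sets of seed
    metabolites -- exogenously available nutrients -- that render a metabolic
    objective satisfiable in a genome-scale metabolic network. Producibility is
    modelled either under the Boolean network-expansion (scope) semantics,
    under a hybrid semantics combining network expansion with flux balance
    analysis (FBA), or both. Includes SBML import/export with fbc flux bounds,
    model-network reconciliation (reversible-reaction splitting, backward
    reactions, import blocking), scope computation with an optional
    no-accumulation constraint, an LP-based FBA layer with seed injection,
    several enumeration engines (reasoning, hybrid-filter, guess-and-check
    with and without diversification, full hybrid search), a brute-force
    testing oracle, solution-diversity statistics, synthetic network
    generators, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
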