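Package: metabmatrix
Title: Layered Metabolic-Health Tier Classification for Packaged Foods
Version: 0.9.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A declarative, fully traceable rule engine that classifies
    consumer packaged-food products into progressive metabolic-health
    tiers (III up to I-A). Products are hierarchical JSON documents with
    nested components and ingredient statements; the engine performs
    assumption-tracked nutrient rollup to a per-serving profile,
    normalizes ingredient statements against a canonical lexicon
    (synonyms, E-numbers, misspellings, group names, modifiers), detects
    Big 8/9 allergens, evaluates a layered criteria configuration in
    which harm-reduction rules gate every ascent and positive attributes
    can never average away failures, and renders per-product reports and
    a portfolio overview together with concrete recommendations for
    reaching the next tier. Ships a reconstructed 38-criterion default
    configuration, a seeded synthetic portfolio generator, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
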