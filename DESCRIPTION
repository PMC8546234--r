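Package: obodash
Title: Automated OBO Foundry Principle Checks and Dashboard Reports
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "maintainer@example.org", role = c("aut", "cre"))
Description: Validation suite for biomedical ontology projects in the style of
    the OBO Foundry dashboard. Parses and validates curated registry metadata
    records against the minimal registry model, runs the thirteen automatable
    OBO Foundry principle checks (openness, common format, URI/identifier
    space, versioning, scope, textual definitions, relations reuse,
    documentation, plurality of users, locus of authority, naming conventions,
    maintenance, responsiveness) over OWL documents serialized as RDF/XML or
    Turtle, and assembles the per-ontology results into a dashboard grid
    renderable as HTML, JSON or TSV with per-ontology detail reports. Ships a
    deterministic fixture generator that produces clean or single-fault
    registry records and ontologies so the whole suite is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    curl,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
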