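Package: flat2biopax
Title: Convert Tabular Molecular Interaction Files to BioPAX Level 3 OWL
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Converts plain-text, tab-delimited molecular interaction records
    (signaling reactions, protein-protein interactions, transcription
    factor-target relations, and simple interaction format networks) into
    BioPAX Level 3 individuals and writes them as a deterministic OWL
    (RDF/XML) document. Input lines are classified into fifteen biochemical
    reaction categories by a user-editable plain-text rules file; the
    resulting ontology graph is structurally deduplicated with
    content-addressed identifiers so that output is byte-identical across
    runs and independent of input line order. Includes a seeded fixture
    generator for all reaction categories and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
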