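# flat2biopax

Convert plain-text, tab-delimited molecular interaction tables into BioPAX
Level 3 OWL (RDF/XML).

## The problem

Most curated interaction data — cell-signaling reactions, kinase–substrate
relations, transcription factor–target maps, protein–protein interaction
networks — lives in flat files and spreadsheets, not in the exchange formats
that pathway databases and analysis tools consume. BioPAX Level 3 is the
community OWL ontology for pathways and gene regulation, but writing BioPAX
by hand is far beyond what most curators will do. `flat2biopax` closes that
gap for anyone with a tab-delimited interaction list: parse, classify, and
emit standards-conformant BioPAX individuals.

## What it does

Each input line describes one directed interaction: a source entity, a
target entity, an interaction-type token, and optionally Swiss-Prot
accessions (human and mouse), entity types, cellular locations, a signed
effect (activating / inhibiting / neutral), and a PubMed id. Four dialects
are accepted:

| template        | columns                                        |
|-----------------|------------------------------------------------|
| `sig` (default) | `SN SH SM ST SL TN TH TM TT TL E TI ID` (13, tab-separated) |
| `source_target` | `SN TN E TI [ID]`                              |
| `tf_target`     | TF name, target gene name, optional PubMed id  |
| `sif`           | source, relation, one or more targets (simple interaction format) |

A plain-text **rules file** (`TI_PATTERN [| ST=PATTERN] [| TT=PATTERN] ->
CATEGORY`, case-insensitive globs, first match wins) classifies every record
into one of **15 reaction categories**: binding, kinase phosphorylation,
dephosphorylation, guanine nucleotide exchange (GEF), GTPase activation
(GAP), ubiquitination, deubiquitination, sumoylation, phospholipase-C
cleavage of PIP2 into IP3 and DAG, three proteolytic cleavage variants,
unspecified protein–protein interaction, transcription, and transcription
factor promoter binding. Unmatched records fall back to the protein–protein
interaction catch-all, and the run report counts those fallbacks. A default
rules file covering all 15 categories ships with the package
(`default_rules_file()`).

Each category has a fixed BioPAX structure — e.g. kinase phosphorylation
becomes a `BiochemicalReaction` whose right side carries a
`ModificationFeature` ("phosphorylated residue") plus a `Catalysis` by the
kinase; transcription becomes a `TemplateReaction` producing the target's
RNA, regulated by a `TemplateReactionRegulation` signed by the effect
column.

Two engineering properties matter for data exchange:

* **Structural deduplication.** Every element gets a canonical key — a
  bottom-up content hash over its class, literals, and children — and the
  model keeps exactly one element per key. The same protein appearing on a
  thousand lines yields one `ProteinReference`; converting a file
  concatenated with itself yields exactly the same model.
* **Deterministic output.** Identifiers are content-addressed
  (`Protein_<16-hex-hash>`), elements and properties serialize in byte
  order, so identical inputs give byte-identical OWL files and permuting
  input lines does not change a single triple.

## Worked example

```r
library(flat2biopax)

# six sig-dialect lines covering three reaction categories
generate_fixture("example.sig",
                 categories = c("BINDING", "KINASE_PHOSPHORYLATION", "TRANSCRIPTION"),
                 n_per_category = 2, seed = 42)
report <- convert_file("example.sig", "example.owl", overwrite = TRUE)
report
```

```
BioPAX conversion report
  input:     example.sig (template: sig)
  output:    example.owl
  lines read 6 = blank/comment 0 + malformed 0 + converted 6
  records built: 6 (fallback classifications: 0)
  reaction categories:
    BINDING                      2
    KINASE_PHOSPHORYLATION       2
    TRANSCRIPTION                2
  model elements: 44 across 16 BioPAX classes
```

Six lines became 44 deduplicated individuals: the four pool proteins appear
in several reactions but are instantiated once per distinct state, and every
line contributed exactly one interaction-level element (`ComplexAssembly`,
`BiochemicalReaction` + `Catalysis`, or `TemplateReaction` +
`TemplateReactionRegulation`). The output begins:

```xml
<?xml version="1.0" encoding="UTF-8"?>
<rdf:RDF
 xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"
 xmlns:owl="http://www.w3.org/2002/07/owl#"
 xmlns:xsd="http://www.w3.org/2001/XMLSchema#"
 xmlns:bp="http://www.biopax.org/release/biopax-level3.owl#"
 xml:base="http://flat2biopax.org/model">
<owl:Ontology rdf:about="">
  <owl:imports rdf:resource="http://www.biopax.org/release/biopax-level3.owl#"/>
</owl:Ontology>
<bp:BiochemicalReaction rdf:about="#BiochemicalReaction_798fc70c9fa5c07d">
  <bp:left rdf:resource="#Protein_1019d757911bb1d8"/>
  <bp:right rdf:resource="#Protein_95212b0e11e64479"/>
  ...
```

From a shell, the same conversion is:

```sh
Rscript inst/cli/flat2biopax -in:example.sig -out:example.owl -r:rules.txt -o
```

(`-o` permits overwriting; without it an existing output file is refused.
`-t:source_target`, `-t:tf_target`, or `-t:sif` select the other dialects.)

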