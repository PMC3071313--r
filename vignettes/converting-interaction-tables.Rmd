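---
title: "Converting tabular interaction data to BioPAX Level 3"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Converting tabular interaction data to BioPAX Level 3}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flat2biopax)
```

## The conversion model

`flat2biopax` treats a flat interaction file as a stream of typed statements:
*source entity* → *interaction type* → *target entity*, optionally annotated
with accessions, entity types, cellular locations, a signed effect, and a
PubMed reference. Conversion is three pure stages per line:

1. **Parse.** The line is split on the dialect's delimiter and mapped
   positionally onto the thirteen-field interaction record. Placeholder
   tokens (`""`, `-`, `NA`, `None`, case-insensitive) become absent fields;
   the effect is normalized to one of `activating` / `inhibiting` /
   `neutral`.
2. **Classify.** An ordered rules file maps the interaction-type token
   (optionally gated on the source/target entity-type tokens) to one of 15
   reaction categories. First match wins; no match falls back to the
   unspecified protein–protein interaction category, and the run report
   counts the fallbacks so silent misclassification is visible.
3. **Build.** Each category has a fixed BioPAX Level 3 structure
   (documented in `?build_interaction`); the builders add the individuals to
   a deduplicating model, which is finally serialized as RDF/XML.

The pipeline assumes each line is an independent assertion: no cross-line
state is carried except the deduplicating model itself. Malformed lines are
skipped and logged rather than aborting the run, because hand-curated flat
files routinely contain stray lines; the report's arithmetic invariant
(`lines_read = blank + malformed + converted`) keeps the accounting honest.

## Input dialects

The `sig` dialect's 13-column layout (`SN SH SM ST SL TN TH TM TT TL E TI
ID`) is fixed. The `source_target` and `tf_target` layouts are this
package's interpretation of minimal source/target formats:

* `source_target`: `SN TN E TI [ID]` — only the reaction type is described;
  entity types are absent and default to protein at build time. The PubMed
  id alone is optional: a record without an interaction type would be
  unusable, so arity is 4–5 rather than allowing the type to be dropped.
* `tf_target`: TF name, target gene name, optional PubMed id. Every line is
  a ChIP-seq-style transcription-factor → gene statement, so the parser
  fixes source type `transcription factor`, target type `gene`, and
  interaction type `transcription`.
* `sif` follows the Cytoscape simple-interaction-format convention: source,
  relation, one or more targets, delimited by tabs or runs of whitespace; a
  multi-target line expands to one record per target. Because of this
  expansion `parse_line()` always returns a *list* of records.

A single tab is the canonical delimiter for the first three dialects, which
is what lets names, types and location terms contain spaces.

## Classification rules

The rules language is deliberately small: one rule per line,
`TI_PATTERN [| ST=PATTERN] [| TT=PATTERN] -> CATEGORY`, `#` comments,
case-insensitive globs with `*` and `?`. First-match-wins mirrors ordered
conditional dispatch and makes rule interaction predictable: specific rules
(e.g. `phosphorylation | ST=kinase`) are simply written above general ones.
Matching on effect or location is not supported; those fields influence the
built structure, not the category. The shipped `rules.txt` maps at least one
token to every category and is meant to be copied and edited.

## Deduplication semantics

The model guarantees that no two elements are structurally identical, where
identity is **deep**: same class, same multiset of literal properties, and
same multiset of (property, child) pairs, recursively. Literals participate
in the comparison deliberately — comparing only children would merge, for
example, two proteins that share a reference but differ in display name or
state. Each element's canonical key is a 64-bit content hash (xxhash64) of a
canonical serialization: class name, byte-sorted literal pairs, byte-sorted
(property, child-key) pairs. Keys are computed bottom-up at construction
time, which has two consequences:

* the child graph is acyclic by construction (an element's children must be
  fully built before it exists), so cycle handling never arises; and
* the key — and therefore the element's identifier,
  `<class>_<16-hex-key>` — is independent of the order in which literals or
  children were attached and of the order of input lines.

Content-addressed identifiers rather than a running counter are what make
output byte-deterministic and line-order invariant: a shared sub-element
mints the same URI no matter which line created it first. A 64-bit hash
admits collisions in principle; at the scale this tool targets (tens of
thousands of elements, i.e. ~10^9 unordered pairs against 2^64 hash values)
the collision probability is negligible, and the test suite cross-checks key
equality against an independent recursive structural-equality oracle on
every element pair of a generated model.

## The category → structure mapping

Choices where BioPAX permits alternatives:

* **Accessions.** The human Swiss-Prot accession becomes a
  `UnificationXref`, the mouse accession a `RelationshipXref` on the same
  entity reference: one reference cannot *unify* to two species' database
  records.
* **Modifications.** Phosphorylation, ubiquitination and sumoylation add a
  `ModificationFeature` whose `SequenceModificationVocabulary` term is a
  display string ("phosphorylated residue", "ubiquitinylated residue",
  "sumoylated residue"); removal reactions are the mirror image, so exactly
  one side of the reaction carries the feature. Resolving terms to MOD
  ontology ids is out of scope.
* **Cleavage.** Products carry a `FragmentFeature` and a display-name suffix
  (" (cleaved)" or " (active)"); the cysteine variant annotates its fragment
  feature with a comment so it remains structurally distinct from plain
  inactivating cleavage. Deactivating cleavages fix the catalysis control
  type to `INHIBITION`, activating cleavage to `ACTIVATION`.
* **Effect policy.** Elsewhere, `activating`/`inhibiting` map to
  `ACTIVATION`/`INHIBITION`; `neutral` or absent effects keep the control
  element but omit `controlType`, preserving the record's (lack of) sign
  rather than asserting activation.
* **Transcription.** The product is the target's `Rna` when the target type
  maps to DNA/gene — the direct product of transcription — while
  `TF_PROMOTER_BINDING` is modeled as a `ComplexAssembly`, so both
  transcription-related categories are honored distinctly.
* **Small molecules.** GDP, GTP, PIP2, IP3 and DAG are `SmallMolecule`
  entities with fixed names and no ChEBI references; complex display names
  sort their member names so naming is order-independent.
* **References to literature** are bare `PublicationXref` individuals
  (db `PubMed`) on the interaction element; Evidence objects are not
  emitted.

## Serialization

Output is RDF/XML only — the lingua franca of BioPAX tooling. The writer
emits a standard Level 3 ontology header (`owl:imports` of the BioPAX Level
3 OWL), one typed node per element at `base_uri + "#" + local_id`, literals
as `xsd:string`-typed properties, and children as `rdf:resource` links.
Elements are ordered by byte order of their identifiers and properties by
byte order of (predicate, value); all sorting uses radix (C-locale) order so
output does not depend on the session locale. The default `base_uri` is a
fixed constant so outputs are comparable across machines; override it via
`convert_file(base_uri = ...)` or `--base-uri=`.

## The fixture generator

`generate_fixture()` is the package's synthetic data source. It emulates the
shape of curated signaling tables: a pool of entities (about one per three
lines by default) reused across lines so deduplication is actually
exercised; consistent name ↔ accession pairings; category-appropriate
interaction-type and entity-type tokens that classify correctly under the
shipped rules; random effects and eight-digit PubMed ids. It does **not**
emulate the messiness of real curation — inconsistent capitalization,
synonym collisions (two names for one protein defeat structural
deduplication by design), wrong accessions, or free-text interaction types
needing fuzzy rules. Passing tests therefore demonstrate the converter's
structural contracts, not robustness to dirty vocabularies; on real data the
fallback count in the run report is the first thing to inspect.

All randomness is seeded and the generator restores the global RNG state, so
fixtures are reproducible byte-for-byte.

## Problem sizes and performance

The test suite exercises conversions from single lines up to files of about
1,000 lines for idempotence properties (five seeds), all-pairs
hash-vs-oracle comparison on models of up to 200 elements, and one
10,000-line run as a throughput check, which completes in well under a
minute on a single CPU; memoization of entity construction and of
(interaction type, source type, target type) → category lookups keeps the
per-line cost low. Models are held fully in memory; tens of thousands of
lines are comfortable, but the design is not aimed at multi-million-edge
graphs.

## Known limitations

* BioPAX class coverage is limited to what the 15 categories need: no
  stoichiometry, no `Pathway` step containers, no experimental-form detail.
* Vocabulary terms (cellular locations, modification terms) are plain
  strings, not resolved to GO/MOD/ChEBI identifiers.
* The converter writes BioPAX; it does not read or validate existing BioPAX
  documents.
* Template layouts are fixed registry entries; there is no header
  auto-detection or user-defined column mapping.
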