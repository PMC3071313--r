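# Independent oracles and hand-built fixtures shared across tests.

# Recursive structural-equality oracle: deep comparison over class, literal
# multiset, and child multiset (matched greedily per property). Deliberately
# independent of canonical_key()/hashing.
struct_equal <- function(a, b) {
  if (a$class_name != b$class_name) {
    return(FALSE)
  }
  lit_strings <- function(e) {
    if (!length(e$literals)) {
      return(character(0))
    }
    sort(paste0(names(e$literals), "=", unlist(e$literals, use.names = FALSE)),
         method = "radix")
  }
  if (!identical(lit_strings(a), lit_strings(b))) {
    return(FALSE)
  }
  if (length(a$children) != length(b$children)) {
    return(FALSE)
  }
  remaining <- b$children
  for (i in seq_along(a$children)) {
    prop <- names(a$children)[i]
    hit <- 0L
    for (j in seq_along(remaining)) {
      if (names(remaining)[j] == prop && struct_equal(a$children[[i]], remaining[[j]])) {
        hit <- j
        break
      }
    }
    if (hit == 0L) {
      return(FALSE)
    }
    remaining <- remaining[-hit]
  }
  TRUE
}

# Canonical interaction-type / source-type / target-type tokens per category,
# chosen to classify under the shipped default rules. Hand-maintained here,
# independent of the package's fixture generator.
category_tokens <- function() {
  list(
    BINDING = c("binding", "protein", "protein"),
    KINASE_PHOSPHORYLATION = c("phosphorylation", "kinase", "protein"),
    DEPHOSPHORYLATION = c("dephosphorylation", "phosphatase", "protein"),
    GUANINE_NUCLEOTIDE_EXCHANGE = c("guanine_nucleotide_exchange", "protein", "protein"),
    GAP_REACTION = c("gap_reaction", "protein", "protein"),
    UBIQUITINATION = c("ubiquitination", "enzyme", "protein"),
    DEUBIQUITINATION = c("deubiquitination", "enzyme", "protein"),
    SUMOYLATION = c("sumoylation", "enzyme", "protein"),
    PLC_CLEAVAGE = c("plc_cleavage", "enzyme", "chemical"),
    CYSTEINE_CLEAVAGE = c("cysteine_cleavage", "enzyme", "protein"),
    INACTIVATING_CLEAVAGE = c("inactivating_cleavage", "enzyme", "protein"),
    ACTIVATING_CLEAVAGE = c("activating_cleavage", "enzyme", "protein"),
    PROTEIN_PROTEIN_INTERACTION = c("pp", "protein", "protein"),
    TRANSCRIPTION = c("transcription", "transcription factor", "gene"),
    TF_PROMOTER_BINDING = c("tf_promoter_binding", "transcription factor", "protein")
  )
}

# One hand-written sig line per category, all entities/locations/PubMed ids
# distinct across lines (no cross-line entity sharing), effect "activating".
hand_sig_line <- function(category, i) {
  tok <- category_tokens()[[category]]
  paste(
    sprintf("SRC%02d", i), sprintf("P1%04d", i), sprintf("Q1%04d", i),
    tok[2], sprintf("compartment_s%02d", i),
    sprintf("TGT%02d", i), sprintf("P2%04d", i), sprintf("Q2%04d", i),
    tok[3], sprintf("compartment_t%02d", i),
    "activating", tok[1], sprintf("%d", 30000000L + i),
    sep = "\t"
  )
}

hand_fixture_lines <- function() {
  cats <- reaction_categories()
  vapply(seq_along(cats), function(i) hand_sig_line(cats[i], i), character(1))
}

write_lines_file <- function(lines, path = tempfile()) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con = con, sep = "\n", useBytes = TRUE)
  path
}

# Hand-enumerated element counts added by one hand_sig_line() record of each
# category converted into a fresh model (entities distinct, both accessions,
# both locations, effect activating, PubMed id present). Derived by walking
# the category -> structure mapping by hand.
expected_census_by_category <- function() {
  protein_pair <- c(
    Protein = 2, ProteinReference = 2, UnificationXref = 2,
    RelationshipXref = 2, CellularLocationVocabulary = 2
  )
  modification <- c(
    Protein = 3, ProteinReference = 2, UnificationXref = 2,
    RelationshipXref = 2, CellularLocationVocabulary = 2,
    ModificationFeature = 1, SequenceModificationVocabulary = 1,
    BiochemicalReaction = 1, Catalysis = 1, PublicationXref = 1
  )
  nucleotide_swap <- c(
    protein_pair, SmallMolecule = 2, SmallMoleculeReference = 2, Complex = 2,
    BiochemicalReaction = 1, Catalysis = 1, PublicationXref = 1
  )
  cleavage <- c(
    Protein = 3, ProteinReference = 2, UnificationXref = 2,
    RelationshipXref = 2, CellularLocationVocabulary = 2, FragmentFeature = 1,
    BiochemicalReaction = 1, Catalysis = 1, PublicationXref = 1
  )
  binding <- c(protein_pair, Complex = 1, ComplexAssembly = 1, PublicationXref = 1)
  list(
    BINDING = binding,
    KINASE_PHOSPHORYLATION = modification,
    DEPHOSPHORYLATION = modification,
    GUANINE_NUCLEOTIDE_EXCHANGE = nucleotide_swap,
    GAP_REACTION = nucleotide_swap,
    UBIQUITINATION = modification,
    DEUBIQUITINATION = modification,
    SUMOYLATION = modification,
    PLC_CLEAVAGE = c(
      Protein = 1, ProteinReference = 1, UnificationXref = 1,
      RelationshipXref = 1, CellularLocationVocabulary = 1,
      SmallMolecule = 3, SmallMoleculeReference = 3,
      BiochemicalReaction = 1, Catalysis = 1, PublicationXref = 1
    ),
    CYSTEINE_CLEAVAGE = cleavage,
    INACTIVATING_CLEAVAGE = cleavage,
    ACTIVATING_CLEAVAGE = cleavage,
    PROTEIN_PROTEIN_INTERACTION = c(
      protein_pair, MolecularInteraction = 1, PublicationXref = 1
    ),
    TRANSCRIPTION = c(
      Protein = 1, ProteinReference = 1, Rna = 1, RnaReference = 1,
      UnificationXref = 2, RelationshipXref = 2,
      CellularLocationVocabulary = 2, TemplateReaction = 1,
      TemplateReactionRegulation = 1, PublicationXref = 1
    ),
    TF_PROMOTER_BINDING = binding
  )
}

# Combined census of the 15-line hand fixture: the per-category sums, minus
# the elements shared across lines (GDP and GTP small molecules + their
# references between the two nucleotide-swap lines; the phospho and ubiquitin
# modification vocabularies AND their enclosing ModificationFeatures between
# each add/remove pair, since the feature has no other content; and the plain
# FragmentFeature between the two non-cysteine cleavage lines).
expected_census_combined <- function() {
  tables <- expected_census_by_category()
  all_classes <- sort(unique(unlist(lapply(tables, names))), method = "radix")
  total <- setNames(numeric(length(all_classes)), all_classes)
  for (tab in tables) {
    total[names(tab)] <- total[names(tab)] + tab
  }
  shared <- c(
    SmallMolecule = 2, SmallMoleculeReference = 2,
    SequenceModificationVocabulary = 2, ModificationFeature = 2,
    FragmentFeature = 1
  )
  total[names(shared)] <- total[names(shared)] - shared
  storage.mode(total) <- "integer"
  total
}

# Census as plain named integer vector for comparisons.
as_census_vec <- function(x) {
  setNames(as.integer(x), names(x))
}

sum_census <- function(report) sum(report$census)

interaction_classes <- c(
  "BiochemicalReaction", "ComplexAssembly", "MolecularInteraction",
  "TemplateReaction"
)

n_interactions <- function(cs) {
  sum(cs[intersect(names(cs), interaction_classes)])
}

# Extract (subject, predicate, object) triples from an emitted OWL file via
# the generic XML parser, for line-order-invariance checks.
owl_triples <- function(path) {
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_children(doc)
  out <- character(0)
  for (nd in nodes) {
    subj <- xml2::xml_attr(nd, "about")
    type <- xml2::xml_name(nd, ns = xml2::xml_ns(doc))
    out <- c(out, paste(subj, "rdf:type", type))
    for (pr in xml2::xml_children(nd)) {
      pred <- xml2::xml_name(pr, ns = xml2::xml_ns(doc))
      obj <- xml2::xml_attr(pr, "resource")
      if (is.na(obj)) {
        obj <- xml2::xml_text(pr)
      }
      out <- c(out, paste(subj, pred, obj))
    }
  }
  sort(out, method = "radix")
}
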