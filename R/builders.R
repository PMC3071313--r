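# Translate one classified interaction record into BioPAX Level 3
# individuals. One fixed mapping per reaction category:
#
#   BINDING / TF_PROMOTER_BINDING -> ComplexAssembly (left: both entities,
#     right: a Complex of both, named "A:B" with member names sorted)
#   KINASE_PHOSPHORYLATION / UBIQUITINATION / SUMOYLATION ->
#     BiochemicalReaction adding a ModificationFeature to the target,
#     catalyzed by the source; DEPHOSPHORYLATION / DEUBIQUITINATION are the
#     mirror (feature on the left)
#   GUANINE_NUCLEOTIDE_EXCHANGE -> Complex(target,GDP) -> Complex(target,GTP),
#     catalyzed by the GEF; GAP_REACTION is the reverse swap
#   PLC_CLEAVAGE -> PIP2 -> IP3 + DAG, catalyzed by the source
#   CYSTEINE_CLEAVAGE / INACTIVATING_CLEAVAGE / ACTIVATING_CLEAVAGE ->
#     BiochemicalReaction producing a FragmentFeature-marked product,
#     catalysis fixed INHIBITION (deactivating) or ACTIVATION (activating)
#   PROTEIN_PROTEIN_INTERACTION -> MolecularInteraction, no control
#   TRANSCRIPTION -> TemplateReaction producing the target's RNA, regulated
#     by the source via TemplateReactionRegulation

.ENTITY_CLASS_MAP <- c(
  kinase = "Protein", phosphatase = "Protein", protein = "Protein",
  enzyme = "Protein", ligand = "Protein", receptor = "Protein",
  "transcription factor" = "Protein",
  gene = "Dna", dna = "Dna",
  rna = "Rna", mrna = "Rna",
  "small molecule" = "SmallMolecule", metabolite = "SmallMolecule",
  chemical = "SmallMolecule",
  complex = "Complex"
)

.REFERENCE_CLASS <- c(
  Protein = "ProteinReference", Dna = "DnaReference", Rna = "RnaReference",
  SmallMolecule = "SmallMoleculeReference"
)

#' Map an entity-type token to a BioPAX physical entity class
#'
#' Kinases, phosphatases, enzymes, ligands, receptors and plain proteins map
#' to `Protein`; genes and DNA to `Dna`; (m)RNA to `Rna`; small molecules,
#' metabolites and chemicals to `SmallMolecule`; complexes to `Complex`.
#' Unknown or absent tokens default to `Protein` (the mapping is total).
#'
#' @param type_token Entity-type token or `NA`.
#' @return A BioPAX class name.
#' @export
entity_class_for <- function(type_token) {
  if (is.na(type_token) || !nzchar(type_token)) {
    return("Protein")
  }
  hit <- unname(.ENTITY_CLASS_MAP[tolower(trimws(type_token))])
  if (is.na(hit)) "Protein" else hit
}

#' Map an effect token to a BioPAX controlType literal
#'
#' `activating` maps to `"ACTIVATION"`, `inhibiting` to `"INHIBITION"`;
#' `neutral` or absent yields `NA` (no controlType literal is emitted, so a
#' neutral record keeps its control element but stays unsigned). The cleavage
#' categories override this with their fixed control type.
#'
#' @param effect Effect token or `NA`.
#' @return `"ACTIVATION"`, `"INHIBITION"`, or `NA_character_`.
#' @export
#' @examples
#' effect_to_control_type("activating")
#' effect_to_control_type("neutral")
effect_to_control_type <- function(effect) {
  if (is.na(effect)) {
    return(NA_character_)
  }
  switch(tolower(effect),
    activating = "ACTIVATION",
    inhibiting = "INHIBITION",
    neutral = NA_character_,
    .bpx_error(
      "flat2biopax_value_error",
      sprintf("effect '%s' is not one of activating/inhibiting/neutral", effect),
      token = effect
    )
  )
}

#' Extract one side of a record as an entity descriptor
#'
#' @param r An `interaction_record`.
#' @param side `"source"` or `"target"`.
#' @return List with `name`, `acc_human`, `acc_mouse`, `entity_type`,
#'   `location`, suitable for [build_entity()].
#' @export
entity_descriptor <- function(r, side = c("source", "target")) {
  side <- side[1]
  if (!side %in% c("source", "target")) {
    stop("side must be 'source' or 'target'")
  }
  if (side == "source") {
    list(name = r$source_name, acc_human = r$source_acc_human,
         acc_mouse = r$source_acc_mouse, entity_type = r$source_type,
         location = r$source_location)
  } else {
    list(name = r$target_name, acc_human = r$target_acc_human,
         acc_mouse = r$target_acc_mouse, entity_type = r$target_type,
         location = r$target_location)
  }
}

#' Build a physical entity and its reference in a model
#'
#' Creates (deduplicating via [add_or_reuse()]) the physical entity of the
#' class mapped from the descriptor's type token, with `displayName` the
#' descriptor name (plus `name_suffix`). Protein/Dna/Rna/SmallMolecule
#' entities carry an `entityReference` child of the matching reference class
#' holding a UniProt `UnificationXref` for the human accession and a UniProt
#' `RelationshipXref` for the mouse accession, when present; a
#' `cellularLocation` vocabulary child is attached when the location is
#' present, and each element of `features` via the `feature` property.
#'
#' @param d Entity descriptor: list with `name`, `acc_human`, `acc_mouse`,
#'   `entity_type`, `location` (see the `sig` template columns).
#' @param m A `biopax_model`.
#' @param features List of feature elements (`ModificationFeature` /
#'   `FragmentFeature`) to attach.
#' @param class_override Force the physical entity class (used for
#'   transcription products).
#' @param name_suffix Appended to `displayName` only (the entity reference
#'   keeps the unsuffixed name, so cleaved products share their precursor's
#'   reference).
#' @return The deduplicated entity `biopax_element`.
#' @export
build_entity <- function(d, m, features = list(), class_override = NULL,
                         name_suffix = "") {
  stopifnot(is.character(d$name), nzchar(d$name))
  cls <- if (is.null(class_override)) entity_class_for(d$entity_type) else class_override

  # memoize on the full descriptor: the constructed subtree is a pure
  # function of these values
  memo_key <- paste(
    c(cls, d$name, name_suffix, d$acc_human, d$acc_mouse, d$location,
      vapply(features, function(f) f$key, character(1))),
    collapse = "\x1f"
  )
  hit <- get0(memo_key, envir = m$entity_cache, inherits = FALSE)
  if (!is.null(hit)) {
    return(hit)
  }

  children <- list()
  ref_cls <- .REFERENCE_CLASS[[cls]]
  if (!is.null(ref_cls)) {
    xrefs <- list()
    if (!is.na(d$acc_human %||% NA_character_)) {
      xrefs <- c(xrefs, list(xref = add_or_reuse(m, bpx_element(
        "UnificationXref", literals = list(db = "UniProt", id = d$acc_human)
      ))))
    }
    if (!is.na(d$acc_mouse %||% NA_character_)) {
      xrefs <- c(xrefs, list(xref = add_or_reuse(m, bpx_element(
        "RelationshipXref", literals = list(db = "UniProt", id = d$acc_mouse)
      ))))
    }
    ref <- add_or_reuse(m, bpx_element(
      ref_cls, literals = list(displayName = d$name), children = xrefs
    ))
    children <- c(children, list(entityReference = ref))
  }
  if (!is.na(d$location %||% NA_character_)) {
    loc <- add_or_reuse(m, bpx_element(
      "CellularLocationVocabulary", literals = list(term = d$location)
    ))
    children <- c(children, list(cellularLocation = loc))
  }
  if (length(features)) {
    fl <- features
    names(fl) <- rep("feature", length(fl))
    children <- c(children, fl)
  }

  out <- add_or_reuse(m, bpx_element(
    cls,
    literals = list(displayName = paste0(d$name, name_suffix)),
    children = children
  ))
  assign(memo_key, out, envir = m$entity_cache)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# -- internal builder helpers -------------------------------------------------

.small_molecule <- function(m, name) {
  build_entity(
    list(name = name, acc_human = NA, acc_mouse = NA,
         entity_type = "small molecule", location = NA),
    m
  )
}

.modification_feature <- function(m, term) {
  voc <- add_or_reuse(m, bpx_element(
    "SequenceModificationVocabulary", literals = list(term = term)
  ))
  add_or_reuse(m, bpx_element(
    "ModificationFeature", children = list(modificationType = voc)
  ))
}

.fragment_feature <- function(m, cysteine = FALSE) {
  lits <- if (cysteine) list(comment = "cleavage at cysteine residue") else list()
  add_or_reuse(m, bpx_element("FragmentFeature", literals = lits))
}

.complex_of <- function(m, members) {
  nm <- paste(sort(vapply(members, function(e) e$literals$displayName, character(1)),
                   method = "radix"),
              collapse = ":")
  names(members) <- rep("component", length(members))
  add_or_reuse(m, bpx_element(
    "Complex", literals = list(displayName = nm), children = members
  ))
}

.pub_xref <- function(m, r) {
  if (is.na(r$pubmed_id)) {
    return(NULL)
  }
  add_or_reuse(m, bpx_element(
    "PublicationXref", literals = list(db = "PubMed", id = r$pubmed_id)
  ))
}

# Interaction-level element plus its optional PublicationXref child.
.interaction <- function(m, class_name, children, r, literals = list()) {
  px <- .pub_xref(m, r)
  if (!is.null(px)) {
    children <- c(children, list(xref = px))
  }
  add_or_reuse(m, bpx_element(class_name, literals = literals, children = children))
}

.control <- function(m, class_name, controller, controlled, control_type) {
  lits <- list()
  if (!is.na(control_type %||% NA_character_)) {
    lits$controlType <- control_type
  }
  add_or_reuse(m, bpx_element(
    class_name, literals = lits,
    children = list(controller = controller, controlled = controlled)
  ))
}

.binding <- function(r, m) {
  src <- build_entity(entity_descriptor(r, "source"), m)
  tgt <- build_entity(entity_descriptor(r, "target"), m)
  cx <- .complex_of(m, list(src, tgt))
  .interaction(m, "ComplexAssembly",
               list(left = src, left = tgt, right = cx), r)
}

# Modification reactions: feature added (direction = "add") or removed.
.modification <- function(r, m, term, direction) {
  src <- build_entity(entity_descriptor(r, "source"), m)
  td <- entity_descriptor(r, "target")
  plain <- build_entity(td, m)
  modified <- build_entity(td, m, features = list(.modification_feature(m, term)))
  sides <- if (direction == "add") {
    list(left = plain, right = modified)
  } else {
    list(left = modified, right = plain)
  }
  rx <- .interaction(m, "BiochemicalReaction", sides, r)
  .control(m, "Catalysis", src, rx, effect_to_control_type(r$effect))
  rx
}

# Nucleotide swap on a G-protein: from-complex(target, from) -> (target, to).
.nucleotide_swap <- function(r, m, from, to) {
  src <- build_entity(entity_descriptor(r, "source"), m)
  tgt <- build_entity(entity_descriptor(r, "target"), m)
  lhs <- .complex_of(m, list(tgt, .small_molecule(m, from)))
  rhs <- .complex_of(m, list(tgt, .small_molecule(m, to)))
  rx <- .interaction(m, "BiochemicalReaction", list(left = lhs, right = rhs), r)
  .control(m, "Catalysis", src, rx, effect_to_control_type(r$effect))
  rx
}

.plc_cleavage <- function(r, m) {
  src <- build_entity(entity_descriptor(r, "source"), m)
  rx <- .interaction(m, "BiochemicalReaction", list(
    left = .small_molecule(m, "PIP2"),
    right = .small_molecule(m, "IP3"),
    right = .small_molecule(m, "DAG")
  ), r)
  .control(m, "Catalysis", src, rx, effect_to_control_type(r$effect))
  rx
}

.cleavage <- function(r, m, suffix, control_type, cysteine = FALSE) {
  src <- build_entity(entity_descriptor(r, "source"), m)
  td <- entity_descriptor(r, "target")
  plain <- build_entity(td, m)
  product <- build_entity(td, m,
                          features = list(.fragment_feature(m, cysteine)),
                          name_suffix = suffix)
  rx <- .interaction(m, "BiochemicalReaction",
                     list(left = plain, right = product), r)
  .control(m, "Catalysis", src, rx, control_type)
  rx
}

.ppi <- function(r, m) {
  src <- build_entity(entity_descriptor(r, "source"), m)
  tgt <- build_entity(entity_descriptor(r, "target"), m)
  .interaction(m, "MolecularInteraction",
               list(participant = src, participant = tgt), r)
}

.transcription <- function(r, m) {
  src <- build_entity(entity_descriptor(r, "source"), m)
  td <- entity_descriptor(r, "target")
  mapped <- entity_class_for(td$entity_type)
  product_class <- if (mapped == "Dna") "Rna" else mapped
  product <- build_entity(td, m, class_override = product_class)
  rx <- .interaction(m, "TemplateReaction", list(product = product), r)
  .control(m, "TemplateReactionRegulation", src, rx,
           effect_to_control_type(r$effect))
  rx
}

#' Build the BioPAX individuals for one classified record
#'
#' Adds exactly one interaction-level element (`BiochemicalReaction`,
#' `ComplexAssembly`, `MolecularInteraction` or `TemplateReaction`) to the
#' model, wired per the category's fixed mapping, plus its `Catalysis` /
#' `TemplateReactionRegulation` control element where the mapping requires
#' one. A `PublicationXref` (db `"PubMed"`) is attached to the interaction
#' when the record carries a PubMed id. Control elements carry `controlType`
#' from [effect_to_control_type()], except the cleavage categories whose
#' control type is fixed (deactivating cleavages: `INHIBITION`; activating
#' cleavage: `ACTIVATION`).
#'
#' @param r An `interaction_record`.
#' @param c A reaction category from [reaction_categories()].
#' @param m A `biopax_model`.
#' @return The interaction-level `biopax_element`.
#' @export
build_interaction <- function(r, c, m) {
  stopifnot(inherits(r, "interaction_record"), inherits(m, "biopax_model"))
  c <- as.character(c)
  if (!c %in% reaction_categories()) {
    .bpx_error("flat2biopax_value_error",
               sprintf("not a buildable reaction category: '%s'", c))
  }
  switch(c,
    BINDING = .binding(r, m),
    TF_PROMOTER_BINDING = .binding(r, m),
    KINASE_PHOSPHORYLATION = .modification(r, m, "phosphorylated residue", "add"),
    DEPHOSPHORYLATION = .modification(r, m, "phosphorylated residue", "remove"),
    UBIQUITINATION = .modification(r, m, "ubiquitinylated residue", "add"),
    DEUBIQUITINATION = .modification(r, m, "ubiquitinylated residue", "remove"),
    SUMOYLATION = .modification(r, m, "sumoylated residue", "add"),
    GUANINE_NUCLEOTIDE_EXCHANGE = .nucleotide_swap(r, m, "GDP", "GTP"),
    GAP_REACTION = .nucleotide_swap(r, m, "GTP", "GDP"),
    PLC_CLEAVAGE = .plc_cleavage(r, m),
    CYSTEINE_CLEAVAGE = .cleavage(r, m, " (cleaved)", "INHIBITION", cysteine = TRUE),
    INACTIVATING_CLEAVAGE = .cleavage(r, m, " (cleaved)", "INHIBITION"),
    ACTIVATING_CLEAVAGE = .cleavage(r, m, " (active)", "ACTIVATION"),
    PROTEIN_PROTEIN_INTERACTION = .ppi(r, m),
    TRANSCRIPTION = .transcription(r, m)
  )
}
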