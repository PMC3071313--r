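# In-memory typed graph of BioPAX Level 3 individuals with structural
# deduplication and content-addressed identifiers.

#' BioPAX Level 3 classes instantiated by this package
#'
#' The closed set of BioPAX Level 3 class names the converter is allowed to
#' instantiate. Attempting to construct an element of any other class is an
#' error: the builders cover signaling reactions, complex assembly,
#' template-directed transcription and their controls, plus the entity
#' reference, feature, vocabulary and cross-reference classes they need.
#'
#' @return Character vector of class names.
#' @export
#' @examples
#' biopax_classes()
biopax_classes <- function() {
  c(
    "Protein", "ProteinReference", "SmallMolecule", "SmallMoleculeReference",
    "Dna", "DnaReference", "Rna", "RnaReference", "Complex",
    "BiochemicalReaction", "ComplexAssembly", "MolecularInteraction",
    "TemplateReaction", "Catalysis", "Control", "TemplateReactionRegulation",
    "ModificationFeature", "FragmentFeature", "SequenceModificationVocabulary",
    "CellularLocationVocabulary", "UnificationXref", "RelationshipXref",
    "PublicationXref", "Pathway"
  )
}

# BioPAX Level 3 property vocabulary used by the builders (lowerCamelCase,
# exactly as in the official Level 3 OWL definition).
.bpx_properties <- c(
  "left", "right", "participant", "controller", "controlled", "controlType",
  "product", "component", "displayName", "xref", "entityReference",
  "feature", "modificationType", "cellularLocation", "db", "id", "term",
  "comment"
)

.bpx_error <- function(subclass, message, ...) {
  stop(structure(
    class = c(subclass, "flat2biopax_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

# Field separators for the canonical serialization; ASCII unit/record
# separators cannot occur in sanitized values.
.KSEP <- "\x1f"
.RSEP <- "\x1e"

# low-overhead hasher resolved once at load time
.xxhash64 <- NULL

.onLoad <- function(libname, pkgname) {
  .xxhash64 <<- digest::getVDigest(algo = "xxhash64")
}

#' Construct a BioPAX element
#'
#' Creates one typed ontology individual. Literal values and child elements
#' are passed as (possibly duplicate-) named lists; property names must come
#' from the BioPAX Level 3 property vocabulary. The canonical key -- a stable
#' content hash over the class name, the sorted literals, and the sorted
#' (property, child-key) pairs -- is computed bottom-up at construction, so
#' children must be fully built first and the resulting child graph is a DAG
#' by construction. Two elements receive equal keys exactly when they are
#' structurally identical (same class, same literal multiset, same child
#' multiset, recursively).
#'
#' @param class_name One of [biopax_classes()].
#' @param literals Named list of scalar character values (names may repeat);
#'   `NA` or empty values are dropped.
#' @param children Named list of `biopax_element` objects (names may repeat).
#' @return A `biopax_element`: list with `class_name`, `literals`, `children`,
#'   `key` (canonical key) and `local_id` (`<class>_<16-hex key>`).
#' @export
#' @examples
#' x <- bpx_element("UnificationXref", literals = list(db = "UniProt", id = "P04637"))
#' x$local_id
bpx_element <- function(class_name, literals = list(), children = list()) {
  if (length(class_name) != 1L || !class_name %in% biopax_classes()) {
    .bpx_error(
      "flat2biopax_class_error",
      sprintf("not an instantiable BioPAX Level 3 class: '%s'", as.character(class_name)[1])
    )
  }

  lit_names <- names(literals)
  keep <- vapply(literals, function(v) length(v) == 1L && !is.na(v) && nzchar(v), logical(1))
  literals <- literals[keep]
  lit_names <- lit_names[keep]
  if (length(literals) && (is.null(lit_names) || any(!nzchar(lit_names)))) {
    .bpx_error("flat2biopax_property_error", "every literal must be named with a BioPAX property")
  }

  chd_names <- names(children)
  if (length(children) && (is.null(chd_names) || any(!nzchar(chd_names)))) {
    .bpx_error("flat2biopax_property_error", "every child must be named with a BioPAX property")
  }
  bad <- setdiff(unique(c(lit_names, chd_names)), .bpx_properties)
  if (length(bad)) {
    .bpx_error(
      "flat2biopax_property_error",
      sprintf("not a BioPAX Level 3 property: %s", paste(bad, collapse = ", "))
    )
  }
  ok_child <- vapply(children, inherits, logical(1), what = "biopax_element")
  if (!all(ok_child)) {
    .bpx_error("flat2biopax_property_error", "children must be biopax_element objects")
  }

  lit_values <- vapply(literals, as.character, character(1))
  # control characters would break the canonical serialization
  if (any(grepl("[\x01-\x1f]", lit_values))) {
    lit_values <- gsub("[\x01-\x1f]", " ", lit_values)
    literals <- as.list(lit_values)
    names(literals) <- lit_names
  }

  lit_part <- if (length(literals)) {
    sort(paste0("L", .KSEP, lit_names, .KSEP, lit_values), method = "radix")
  } else character(0)
  chd_part <- if (length(children)) {
    sort(paste0("C", .KSEP, chd_names, .KSEP,
                vapply(children, function(e) e$key, character(1))),
         method = "radix")
  } else character(0)

  canon <- paste(c(class_name, lit_part, chd_part), collapse = .RSEP)
  key <- .xxhash64(canon, serialize = FALSE)

  structure(
    list(
      class_name = class_name,
      literals = literals,
      children = children,
      key = key,
      local_id = paste0(class_name, "_", substr(key, 1L, 16L))
    ),
    class = "biopax_element"
  )
}

#' Canonical key of an element
#'
#' Returns the content-addressed canonical key: a stable hash over the class
#' name, the lexicographically sorted literals, and the lexicographically
#' sorted (property, child-key) pairs, computed bottom-up. Key equality is
#' deep structural identity and is invariant under the order in which
#' literals and children were attached.
#'
#' @param e A `biopax_element`.
#' @return The key as a 16-character hex string.
#' @export
canonical_key <- function(e) {
  stopifnot(inherits(e, "biopax_element"))
  e$key
}

#' Create an empty BioPAX model
#'
#' A model owns a set of elements indexed by canonical key: no two elements
#' in a model share a key, so structurally identical individuals produced
#' from different input lines collapse to one node.
#'
#' @param base_uri Base URI under which element URIs are minted on export.
#' @return A `biopax_model` (environment).
#' @export
#' @examples
#' m <- bpx_model()
#' bpx_n_elements(m)
bpx_model <- function(base_uri = "http://flat2biopax.org/model") {
  m <- new.env(parent = emptyenv())
  m$index <- new.env(parent = emptyenv(), size = 4096L)
  # builder-level memo: entity-descriptor string -> element (avoids
  # reconstructing identical entity subtrees for recurring participants)
  m$entity_cache <- new.env(parent = emptyenv(), size = 1024L)
  m$base_uri <- base_uri
  m$n <- 0L
  class(m) <- "biopax_model"
  m
}

#' Add an element to a model, reusing any structural duplicate
#'
#' If an element with the same canonical key is already in the model it is
#' returned and `e` is discarded; otherwise `e` is inserted and indexed. The
#' element count grows by 0 or 1.
#'
#' @param m A `biopax_model`.
#' @param e A fully constructed `biopax_element` (all children attached).
#' @return The model's element for `e`'s canonical key.
#' @export
add_or_reuse <- function(m, e) {
  if (!inherits(m, "biopax_model") || !inherits(e, "biopax_element")) {
    stop("add_or_reuse() needs a biopax_model and a biopax_element")
  }
  hit <- get0(e$key, envir = m$index, inherits = FALSE)
  if (!is.null(hit)) {
    return(hit)
  }
  assign(e$key, e, envir = m$index)
  m$n <- m$n + 1L
  e
}

#' All elements of a model
#'
#' @param m A `biopax_model`.
#' @return Unordered list of `biopax_element` objects.
#' @export
bpx_elements <- function(m) {
  stopifnot(inherits(m, "biopax_model"))
  as.list(m$index, all.names = TRUE)
}

#' Number of elements in a model
#' @param m A `biopax_model`.
#' @return Integer count.
#' @export
bpx_n_elements <- function(m) {
  stopifnot(inherits(m, "biopax_model"))
  m$n
}

#' Per-class instance census of a model
#'
#' @param m A `biopax_model`.
#' @return Named integer vector, class name -> count, sorted by class name;
#'   the sum equals the total element count. Empty model gives an empty
#'   vector.
#' @export
census <- function(m) {
  els <- bpx_elements(m)
  if (!length(els)) {
    return(stats::setNames(integer(0), character(0)))
  }
  cls <- vapply(els, function(e) e$class_name, character(1), USE.NAMES = FALSE)
  tab <- table(cls)
  out <- stats::setNames(as.integer(tab), names(tab))
  out[sort(names(out), method = "radix")]
}

#' @export
print.biopax_element <- function(x, ...) {
  cat(sprintf("<biopax_element> %s (%d literal(s), %d child(ren))\n",
              x$local_id, length(x$literals), length(x$children)))
  invisible(x)
}

#' @export
print.biopax_model <- function(x, ...) {
  cat(sprintf("<biopax_model> %d element(s), base URI %s\n", x$n, x$base_uri))
  cs <- census(x)
  if (length(cs)) {
    for (i in seq_along(cs)) cat(sprintf("  %-32s %d\n", names(cs)[i], cs[i]))
  }
  invisible(x)
}
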