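# Rules file parsing and reaction-category classification.
#
# Grammar, one rule per line:
#   TI_PATTERN [| ST=PATTERN] [| TT=PATTERN] -> CATEGORY
# Patterns are case-insensitive globs ('*' any run, '?' one character) over
# the interaction-type token, optionally gated on the source/target entity
# type tokens. '#' lines are comments. Matching is first-match-wins in file
# order; records matching no rule fall back to PROTEIN_PROTEIN_INTERACTION
# (the catch-all "otherwise unspecified reaction between two proteins").

#' The reaction categories
#'
#' The fifteen biochemical reaction categories the converter can represent:
#' complex formation, kinase phosphorylation and dephosphorylation, guanine
#' nucleotide exchange (GEF) and GTPase activation (GAP), ubiquitination /
#' deubiquitination / sumoylation, phospholipase-C cleavage of PIP2, three
#' proteolytic cleavage variants, unspecified protein-protein interaction,
#' transcription, and transcription-factor promoter binding.
#'
#' @return Character vector of the 15 category tokens.
#' @export
#' @examples
#' reaction_categories()
reaction_categories <- function() {
  c(
    "BINDING", "KINASE_PHOSPHORYLATION", "DEPHOSPHORYLATION",
    "GUANINE_NUCLEOTIDE_EXCHANGE", "GAP_REACTION", "UBIQUITINATION",
    "DEUBIQUITINATION", "SUMOYLATION", "PLC_CLEAVAGE", "CYSTEINE_CLEAVAGE",
    "INACTIVATING_CLEAVAGE", "ACTIVATING_CLEAVAGE",
    "PROTEIN_PROTEIN_INTERACTION", "TRANSCRIPTION", "TF_PROMOTER_BINDING"
  )
}

.FALLBACK_CATEGORY <- "PROTEIN_PROTEIN_INTERACTION"

.glob_rx <- function(pattern) {
  utils::glob2rx(trimws(pattern), trim.tail = FALSE)
}

.rules_syntax_error <- function(line_number, msg) {
  .bpx_error(
    "flat2biopax_rules_syntax",
    sprintf("rules file line %d: %s", line_number, msg),
    line_number = line_number
  )
}

#' Path to the shipped default rules file
#'
#' The packaged `rules.txt` maps at least one interaction-type token to every
#' one of the fifteen reaction categories; users may copy and edit it or
#' write their own from scratch.
#'
#' @return Path to the installed default rules file.
#' @export
default_rules_file <- function() {
  system.file("extdata", "rules.txt", package = "flat2biopax", mustWork = TRUE)
}

#' Load a classification rules file
#'
#' Each non-blank, non-comment line
#' `TI_PATTERN [| ST=PATTERN] [| TT=PATTERN] -> CATEGORY` becomes one rule;
#' file order is preserved and matching is first-match-wins.
#'
#' @param path Rules file path.
#' @return A `biopax_ruleset`: ordered list of rules, each with `ti_pattern`,
#'   optional `st_pattern` / `tt_pattern`, `category`, `source_line`, and
#'   precompiled regexes.
#' @export
load_rules <- function(path) {
  if (!file.exists(path)) {
    .bpx_error("flat2biopax_file_error", sprintf("rules file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  rules <- list()
  for (i in seq_along(lines)) {
    raw <- trimws(lines[i])
    if (!nzchar(raw) || startsWith(raw, "#")) next
    parts <- strsplit(raw, "->", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      .rules_syntax_error(i, "expected exactly one '->'")
    }
    category <- trimws(parts[2])
    if (!category %in% reaction_categories()) {
      .rules_syntax_error(i, sprintf("unknown category '%s'", category))
    }
    clauses <- trimws(strsplit(parts[1], "|", fixed = TRUE)[[1]])
    if (!length(clauses) || !nzchar(clauses[1])) {
      .rules_syntax_error(i, "missing interaction-type pattern")
    }
    rule <- list(
      ti_pattern = clauses[1], ti_rx = .glob_rx(clauses[1]),
      st_pattern = NULL, st_rx = NULL,
      tt_pattern = NULL, tt_rx = NULL,
      category = category, source_line = i
    )
    for (cl in clauses[-1]) {
      m <- regmatches(cl, regexec("^(ST|TT)\\s*=\\s*(.+)$", cl, ignore.case = TRUE))[[1]]
      if (length(m) != 3L) {
        .rules_syntax_error(i, sprintf("bad gate clause '%s' (expected ST=... or TT=...)", cl))
      }
      field <- toupper(m[2])
      if (field == "ST") {
        rule$st_pattern <- m[3]
        rule$st_rx <- .glob_rx(m[3])
      } else {
        rule$tt_pattern <- m[3]
        rule$tt_rx <- .glob_rx(m[3])
      }
    }
    rules[[length(rules) + 1L]] <- rule
  }
  structure(
    list(rules = rules, path = path,
         # memo of (TI, ST, TT) -> category for repeated tokens
         cache = new.env(parent = emptyenv(), size = 256L)),
    class = "biopax_ruleset"
  )
}

.gate_matches <- function(rx, value) {
  if (is.null(rx)) {
    return(TRUE)
  }
  !is.na(value) && grepl(rx, value, ignore.case = TRUE)
}

#' Classify an interaction record
#'
#' Applies the rules in file order; the first rule whose interaction-type
#' pattern matches the record's interaction type and whose source/target type
#' gates (when present) match the record's entity types determines the
#' category. Classification is total: a record matching no rule falls back to
#' `PROTEIN_PROTEIN_INTERACTION`, flagged with attribute `fallback = TRUE` so
#' callers can surface the count.
#'
#' @param r An `interaction_record`.
#' @param rs A `biopax_ruleset` from [load_rules()].
#' @return Category token (never `UNKNOWN`), with logical attribute
#'   `fallback`.
#' @export
#' @examples
#' rs <- load_rules(default_rules_file())
#' rec <- parse_line("A\tpp\tB", template = "sif")[[1]]
#' classify(rec, rs)
classify <- function(r, rs) {
  if (!inherits(r, "interaction_record") || !inherits(rs, "biopax_ruleset")) {
    stop("classify() needs an interaction_record and a biopax_ruleset")
  }
  memo_key <- paste(r$interaction_type, r$source_type, r$target_type, sep = "\x1f")
  hit <- get0(memo_key, envir = rs$cache, inherits = FALSE)
  if (!is.null(hit)) {
    return(hit)
  }
  out <- structure(.FALLBACK_CATEGORY, fallback = TRUE)
  for (rule in rs$rules) {
    if (grepl(rule$ti_rx, r$interaction_type, ignore.case = TRUE) &&
        .gate_matches(rule$st_rx, r$source_type) &&
        .gate_matches(rule$tt_rx, r$target_type)) {
      out <- structure(rule$category, fallback = FALSE)
      break
    }
  }
  assign(memo_key, out, envir = rs$cache)
  out
}

#' @export
print.biopax_ruleset <- function(x, ...) {
  cat(sprintf("<biopax_ruleset> %d rule(s) from %s\n", length(x$rules), x$path))
  invisible(x)
}
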