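# Input template dialects: column layouts for the four accepted flat-file
# formats, and the line parser producing interaction records.

.EFFECTS <- c("activating", "inhibiting", "neutral")
.PLACEHOLDERS <- c("", "-", "na", "none")

.is_absent <- function(x) tolower(x) %in% .PLACEHOLDERS

.template_registry <- list(
  sig = list(
    name = "sig",
    columns = c("SN", "SH", "SM", "ST", "SL", "TN", "TH", "TM", "TT", "TL", "E", "TI", "ID"),
    delimiter = "tab",
    min_arity = 13L,
    max_arity = 13L,
    default = TRUE
  ),
  source_target = list(
    name = "source_target",
    columns = c("SN", "TN", "E", "TI", "ID"),
    delimiter = "tab",
    min_arity = 4L,
    max_arity = 5L,
    default = FALSE
  ),
  tf_target = list(
    name = "tf_target",
    columns = c("SN", "TN", "ID"),
    delimiter = "tab",
    min_arity = 2L,
    max_arity = 3L,
    default = FALSE
  ),
  sif = list(
    name = "sif",
    columns = c("SN", "TI", "TN..."),
    delimiter = "whitespace",
    min_arity = 3L,
    max_arity = NA_integer_,
    default = FALSE
  )
)

#' Registered input template dialects
#'
#' Exactly four tabular dialects are registered: `sig` (13 tab-separated
#' columns SN SH SM ST SL TN TH TM TT TL E TI ID describing source and target
#' entities, effect, interaction type and PubMed id), `source_target`
#' (SN TN E TI \[ID\]), `tf_target` (transcription-factor name, target gene
#' name, optional PubMed id), and `sif` (simple interaction format: source,
#' relation, one or more targets, whitespace-delimited). `sig` is the
#' default.
#'
#' @return Character vector of the four template names, with attribute
#'   `default` naming the default dialect.
#' @export
#' @examples
#' registered_templates()
registered_templates <- function() {
  nm <- names(.template_registry)
  structure(nm, default = nm[vapply(.template_registry, `[[`, logical(1), "default")])
}

#' Column layout of a registered template
#'
#' @param name Template name.
#' @return The template spec: list with `name`, `columns`, `delimiter`,
#'   `min_arity`, `max_arity`, `default`.
#' @export
template_spec <- function(name) {
  spec <- .template_registry[[as.character(name)[1]]]
  if (is.null(spec)) {
    .bpx_error(
      "flat2biopax_unknown_template",
      sprintf("unknown input template '%s' (registered: %s)",
              name, paste(names(.template_registry), collapse = ", "))
    )
  }
  spec
}

# fields are trimmed in bulk by parse_line before this is called
.norm_field <- function(x) {
  if (.is_absent(x)) NA_character_ else x
}

.norm_effect <- function(x, line_number) {
  x <- .norm_field(trimws(x))
  if (is.na(x)) {
    return(NA_character_)
  }
  x <- tolower(x)
  if (!x %in% .EFFECTS) {
    .bpx_error(
      "flat2biopax_value_error",
      sprintf("line %d: effect '%s' is not one of %s",
              line_number, x, paste(.EFFECTS, collapse = "/")),
      line_number = line_number, token = x
    )
  }
  x
}

new_record <- function(source_name, target_name, interaction_type,
                       source_acc_human = NA_character_, source_acc_mouse = NA_character_,
                       source_type = NA_character_, source_location = NA_character_,
                       target_acc_human = NA_character_, target_acc_mouse = NA_character_,
                       target_type = NA_character_, target_location = NA_character_,
                       effect = NA_character_, pubmed_id = NA_character_,
                       line_number = 1L, template = "sig") {
  structure(
    list(
      source_name = source_name, source_acc_human = source_acc_human,
      source_acc_mouse = source_acc_mouse, source_type = source_type,
      source_location = source_location,
      target_name = target_name, target_acc_human = target_acc_human,
      target_acc_mouse = target_acc_mouse, target_type = target_type,
      target_location = target_location,
      effect = effect, interaction_type = interaction_type,
      pubmed_id = pubmed_id,
      line_number = as.integer(line_number), template = template
    ),
    class = "interaction_record"
  )
}

.malformed <- function(line_number, msg) {
  .bpx_error(
    "flat2biopax_malformed_line",
    sprintf("line %d: %s", line_number, msg),
    line_number = line_number
  )
}

.require_field <- function(x, what, line_number) {
  if (is.na(x) || !nzchar(x)) {
    .malformed(line_number, sprintf("missing required field: %s", what))
  }
  x
}

#' Parse one input line into interaction records
#'
#' Splits the line on the dialect's delimiter (a single tab, or runs of
#' whitespace for `sif`), maps fields positionally per the template's column
#' layout, normalizes placeholder tokens (`""`, `-`, `NA`, `None`,
#' case-insensitive) to absent, lower-cases and validates the effect field,
#' and returns the records for the line. All dialects yield one record per
#' line except `sif`, where a multi-target line `A rel B C` expands to one
#' record per trailing target.
#'
#' `tf_target` lines are filled in as transcription-factor/gene records:
#' source type `"transcription factor"`, target type `"gene"`, interaction
#' type `"transcription"`. `source_target` lines leave entity types absent
#' (the builders default absent types to protein).
#'
#' @param line Input line; must not be blank or a `#` comment.
#' @param template Template name (see [registered_templates()]).
#' @param line_number 1-based line number, carried into records and errors.
#' @return List of `interaction_record` objects (length >= 1).
#' @export
#' @examples
#' rec <- parse_line("A\tpp\tB", template = "sif")[[1]]
#' rec$interaction_type
parse_line <- function(line, template = "sig", line_number = 1L) {
  spec <- template_spec(template)
  line_number <- as.integer(line_number)

  fields <- if (spec$delimiter == "tab") {
    strsplit(line, "\t", fixed = TRUE)[[1]]
  } else {
    strsplit(trimws(line), "[ \t]+")[[1]]
  }
  fields <- trimws(fields)
  n <- length(fields)
  if (n < spec$min_arity || (!is.na(spec$max_arity) && n > spec$max_arity)) {
    .malformed(line_number, sprintf(
      "%s template expects %s fields, got %d",
      spec$name,
      if (is.na(spec$max_arity)) sprintf(">= %d", spec$min_arity)
      else if (spec$min_arity == spec$max_arity) sprintf("%d", spec$min_arity)
      else sprintf("%d-%d", spec$min_arity, spec$max_arity),
      n
    ))
  }

  f <- function(i) if (i <= n) .norm_field(fields[i]) else NA_character_

  recs <- switch(
    spec$name,
    sig = list(new_record(
      source_name = .require_field(f(1), "source name (SN)", line_number),
      source_acc_human = f(2), source_acc_mouse = f(3),
      source_type = f(4), source_location = f(5),
      target_name = .require_field(f(6), "target name (TN)", line_number),
      target_acc_human = f(7), target_acc_mouse = f(8),
      target_type = f(9), target_location = f(10),
      effect = .norm_effect(fields[11], line_number),
      interaction_type = .require_field(f(12), "interaction type (TI)", line_number),
      pubmed_id = f(13),
      line_number = line_number, template = "sig"
    )),
    source_target = list(new_record(
      source_name = .require_field(f(1), "source name (SN)", line_number),
      target_name = .require_field(f(2), "target name (TN)", line_number),
      effect = .norm_effect(fields[3], line_number),
      interaction_type = .require_field(f(4), "interaction type (TI)", line_number),
      pubmed_id = f(5),
      line_number = line_number, template = "source_target"
    )),
    tf_target = list(new_record(
      source_name = .require_field(f(1), "transcription factor name", line_number),
      source_type = "transcription factor",
      target_name = .require_field(f(2), "target gene name", line_number),
      target_type = "gene",
      interaction_type = "transcription",
      pubmed_id = f(3),
      line_number = line_number, template = "tf_target"
    )),
    sif = {
      src <- .require_field(f(1), "source name", line_number)
      rel <- .require_field(f(2), "interaction type", line_number)
      lapply(seq.int(3L, n), function(i) {
        new_record(
          source_name = src,
          target_name = .require_field(f(i), "target name", line_number),
          interaction_type = rel,
          line_number = line_number, template = "sif"
        )
      })
    }
  )
  recs
}

#' @export
print.interaction_record <- function(x, ...) {
  cat(sprintf("<interaction_record> %s -[%s]-> %s (%s, line %d)\n",
              x$source_name, x$interaction_type, x$target_name,
              x$template, x$line_number))
  invisible(x)
}
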