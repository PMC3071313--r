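# Seeded generator of syntactically valid input files covering every
# reaction category, used for testing and demonstration.

# canonical interaction-type token and entity types per category, matching
# the shipped default rules file
.FIXTURE_TOKENS <- list(
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

.LOCATIONS <- c("cytoplasm", "nucleus", "plasma membrane", "extracellular region",
                "mitochondrion", "endoplasmic reticulum")

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Generate a deterministic input fixture file
#'
#' Writes a syntactically valid interaction file in the requested template
#' dialect, with `n_per_category` lines per requested reaction category.
#' Names, accessions, locations, effects and PubMed ids are drawn
#' pseudo-randomly from `seed`; the same arguments always produce an
#' identical file. Entities are drawn from a shared pool (default roughly one
#' entity per three lines), so participants recur across lines and exercise
#' the model's structural deduplication. Every line classifies to its
#' intended category under the shipped default rules.
#'
#' For `template = "tf_target"` all lines are transcription-factor/target
#' records regardless of `categories`; for `"sif"` some lines carry multiple
#' targets, which the parser expands to one record each.
#'
#' @param path Output file path.
#' @param categories Reaction categories to cover (default: all 15).
#' @param n_per_category Lines per category (>= 1).
#' @param seed Integer seed; the global RNG state is left untouched.
#' @param template Dialect to emit (`sig`, `source_target`, `tf_target`,
#'   `sif`).
#' @param n_entities Size of the shared entity name pool (default scales with
#'   the number of lines).
#' @return `path`, invisibly.
#' @export
#' @examples
#' f <- tempfile(fileext = ".sig")
#' generate_fixture(f, n_per_category = 2, seed = 42)
#' length(readLines(f))
generate_fixture <- function(path, categories = reaction_categories(),
                             n_per_category = 1L, seed = 1L,
                             template = "sig", n_entities = NULL) {
  stopifnot(n_per_category >= 1L)
  spec <- template_spec(template)
  categories <- match.arg(categories, reaction_categories(), several.ok = TRUE)
  total <- length(categories) * n_per_category
  if (is.null(n_entities)) {
    n_entities <- max(4L, as.integer(ceiling(total / 3)))
  }

  lines <- .with_seed(seed, {
    pool_name <- sprintf("PROT%03d", seq_len(n_entities))
    pool_hu <- sprintf("P%05d", 10000L + seq_len(n_entities))
    pool_mo <- sprintf("Q%05d", 20000L + seq_len(n_entities))
    pool_loc <- sample(.LOCATIONS, n_entities, replace = TRUE)

    cats <- sample(rep(categories, each = n_per_category))
    out <- character(0)
    for (cat in cats) {
      tok <- .FIXTURE_TOKENS[[cat]]
      si <- sample.int(n_entities, 1L)
      ti <- sample.int(n_entities, 1L)
      if (n_entities > 1L) {
        while (ti == si) ti <- sample.int(n_entities, 1L)
      }
      effect <- sample(c("activating", "inhibiting", "neutral"), 1L)
      pmid <- sprintf("%d", sample.int(9999999L, 1L) + 10000000L)
      line <- switch(
        spec$name,
        sig = paste(
          pool_name[si], pool_hu[si], pool_mo[si], tok[2], pool_loc[si],
          pool_name[ti], pool_hu[ti], pool_mo[ti], tok[3], pool_loc[ti],
          effect, tok[1], pmid,
          sep = "\t"
        ),
        source_target = paste(pool_name[si], pool_name[ti], effect, tok[1], pmid,
                              sep = "\t"),
        tf_target = paste(pool_name[si], pool_name[ti], pmid, sep = "\t"),
        sif = {
          extra <- if (stats::runif(1) < 0.3 && n_entities > 2L) {
            pool_name[sample.int(n_entities, 1L)]
          } else NULL
          paste(c(pool_name[si], tok[1], pool_name[ti], extra), collapse = "\t")
        }
      )
      out <- c(out, line)
    }
    out
  })

  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
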