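build_one <- function(category, i = 1L) {
  m <- bpx_model()
  r <- parse_line(hand_sig_line(category, i), "sig", line_number = i)[[1]]
  rx <- build_interaction(r, category, m)
  list(model = m, record = r, interaction = rx)
}

find_elements <- function(m, class_name) {
  Filter(function(e) e$class_name == class_name, bpx_elements(m))
}

test_that("every category builds exactly the hand-enumerated element counts", {
  expected <- expected_census_by_category()
  for (cat in reaction_categories()) {
    got <- census(build_one(cat)$model)
    want <- expected[[cat]]
    want <- want[sort(names(want), method = "radix")]
    expect_identical(as_census_vec(got), as_census_vec(want),
                     label = sprintf("census for %s", cat))
  }
})

test_that("binding produces a two-component complex with a sorted name", {
  m <- build_one("BINDING")$model
  cx <- find_elements(m, "Complex")[[1]]
  expect_length(cx$children, 2L)
  expect_true(all(names(cx$children) == "component"))
  members <- sort(vapply(cx$children, function(e) e$literals$displayName, character(1)),
                  method = "radix")
  expect_identical(cx$literals$displayName, paste(members, collapse = ":"))

  ca <- find_elements(m, "ComplexAssembly")[[1]]
  expect_identical(sum(names(ca$children) == "left"), 2L)
  expect_identical(sum(names(ca$children) == "right"), 1L)
})

test_that("modification reactions put the feature on exactly one side", {
  cases <- list(
    KINASE_PHOSPHORYLATION = c("right", "phosphorylated residue"),
    DEPHOSPHORYLATION = c("left", "phosphorylated residue"),
    UBIQUITINATION = c("right", "ubiquitinylated residue"),
    DEUBIQUITINATION = c("left", "ubiquitinylated residue"),
    SUMOYLATION = c("right", "sumoylated residue")
  )
  for (cat in names(cases)) {
    out <- build_one(cat)
    rx <- out$interaction
    side <- cases[[cat]][1]
    other <- setdiff(c("left", "right"), side)
    featured <- rx$children[[which(names(rx$children) == side)]]
    plain <- rx$children[[which(names(rx$children) == other)]]
    expect_identical(sum(names(featured$children) == "feature"), 1L,
                     label = sprintf("%s featured side", cat))
    expect_identical(sum(names(plain$children) == "feature"), 0L,
                     label = sprintf("%s plain side", cat))
    mf <- featured$children[[which(names(featured$children) == "feature")]]
    expect_identical(mf$class_name, "ModificationFeature")
    expect_identical(mf$children$modificationType$literals$term, cases[[cat]][2])
  }
})

test_that("nucleotide exchange and GAP reactions swap GDP/GTP complexes", {
  complex_smallmol <- function(rx, side) {
    cx <- rx$children[[which(names(rx$children) == side)]]
    sm <- Filter(function(e) e$class_name == "SmallMolecule", cx$children)
    vapply(sm, function(e) e$literals$displayName, character(1), USE.NAMES = FALSE)
  }
  gef <- build_one("GUANINE_NUCLEOTIDE_EXCHANGE")$interaction
  expect_identical(complex_smallmol(gef, "left"), "GDP")
  expect_identical(complex_smallmol(gef, "right"), "GTP")

  gap <- build_one("GAP_REACTION")$interaction
  expect_identical(complex_smallmol(gap, "left"), "GTP")
  expect_identical(complex_smallmol(gap, "right"), "GDP")
})

test_that("phospholipase C cleavage converts PIP2 into IP3 and DAG", {
  rx <- build_one("PLC_CLEAVAGE")$interaction
  left <- rx$children[names(rx$children) == "left"]
  right <- rx$children[names(rx$children) == "right"]
  expect_identical(vapply(left, function(e) e$literals$displayName, character(1),
                          USE.NAMES = FALSE), "PIP2")
  expect_setequal(vapply(right, function(e) e$literals$displayName, character(1),
                         USE.NAMES = FALSE), c("IP3", "DAG"))
})

test_that("cleavage categories fix the control type and suffix the product", {
  cases <- list(
    CYSTEINE_CLEAVAGE = c(" (cleaved)", "INHIBITION"),
    INACTIVATING_CLEAVAGE = c(" (cleaved)", "INHIBITION"),
    ACTIVATING_CLEAVAGE = c(" (active)", "ACTIVATION")
  )
  for (cat in names(cases)) {
    out <- build_one(cat)
    rx <- out$interaction
    product <- rx$children[[which(names(rx$children) == "right")]]
    expect_match(product$literals$displayName,
                 paste0("\\Q", cases[[cat]][1], "\\E$"))
    expect_identical(sum(names(product$children) == "feature"), 1L)
    ctl <- find_elements(out$model, "Catalysis")[[1]]
    expect_identical(ctl$literals$controlType, cases[[cat]][2])
  }
  # cysteine cleavage is structurally distinct from plain inactivating cleavage
  cys <- build_one("CYSTEINE_CLEAVAGE")$model
  frag <- find_elements(cys, "FragmentFeature")[[1]]
  expect_identical(frag$literals$comment, "cleavage at cysteine residue")
  plain_frag <- find_elements(build_one("INACTIVATING_CLEAVAGE")$model,
                              "FragmentFeature")[[1]]
  expect_length(plain_frag$literals, 0L)
  expect_false(frag$key == plain_frag$key)
})

test_that("effect maps to controlType; neutral and absent stay unsigned", {
  expect_identical(effect_to_control_type("activating"), "ACTIVATION")
  expect_identical(effect_to_control_type("inhibiting"), "INHIBITION")
  expect_true(is.na(effect_to_control_type("neutral")))
  expect_true(is.na(effect_to_control_type(NA_character_)))
  expect_error(effect_to_control_type("sometimes"),
               class = "flat2biopax_value_error")

  # inhibiting transcription carries INHIBITION on the regulation element
  m <- bpx_model()
  ln <- sub("\tactivating\t", "\tinhibiting\t", hand_sig_line("TRANSCRIPTION", 1L))
  r <- parse_line(ln, "sig")[[1]]
  build_interaction(r, "TRANSCRIPTION", m)
  trr <- find_elements(m, "TemplateReactionRegulation")[[1]]
  expect_identical(trr$literals$controlType, "INHIBITION")

  # neutral catalysis keeps the control element but omits controlType
  m2 <- bpx_model()
  ln2 <- sub("\tactivating\t", "\tneutral\t", hand_sig_line("KINASE_PHOSPHORYLATION", 1L))
  r2 <- parse_line(ln2, "sig")[[1]]
  build_interaction(r2, "KINASE_PHOSPHORYLATION", m2)
  cat_el <- find_elements(m2, "Catalysis")[[1]]
  expect_null(cat_el$literals$controlType)
})

test_that("every control element has exactly one controller and one controlled", {
  for (cat in setdiff(reaction_categories(),
                      c("BINDING", "TF_PROMOTER_BINDING",
                        "PROTEIN_PROTEIN_INTERACTION"))) {
    m <- build_one(cat)$model
    ctls <- Filter(function(e) e$class_name %in%
                     c("Catalysis", "Control", "TemplateReactionRegulation"),
                   bpx_elements(m))
    expect_length(ctls, 1L)
    nm <- names(ctls[[1]]$children)
    expect_identical(sum(nm == "controller"), 1L, label = cat)
    expect_identical(sum(nm == "controlled"), 1L, label = cat)
  }
})

test_that("entity building maps types, xrefs, and shares references", {
  m <- bpx_model()
  d <- list(name = "KIN1", acc_human = "P00001", acc_mouse = "Q00001",
            entity_type = "kinase", location = "cytoplasm")
  e <- build_entity(d, m)
  expect_identical(e$class_name, "Protein")
  ref <- e$children$entityReference
  expect_identical(ref$class_name, "ProteinReference")
  xcls <- vapply(ref$children[names(ref$children) == "xref"],
                 function(x) x$class_name, character(1), USE.NAMES = FALSE)
  expect_setequal(xcls, c("UnificationXref", "RelationshipXref"))
  expect_identical(e$children$cellularLocation$literals$term, "cytoplasm")

  # gene -> Dna + DnaReference; unknown type defaults to Protein
  g <- build_entity(list(name = "G1", acc_human = NA, acc_mouse = NA,
                         entity_type = "gene", location = NA), m)
  expect_identical(g$class_name, "Dna")
  expect_identical(g$children$entityReference$class_name, "DnaReference")
  u <- build_entity(list(name = "U1", acc_human = NA, acc_mouse = NA,
                         entity_type = "martian", location = NA), m)
  expect_identical(u$class_name, "Protein")

  # rebuilding the same descriptor adds nothing
  before <- census(m)
  build_entity(d, m)
  expect_identical(census(m), before)

  # same protein in two locations shares one reference
  d2 <- modifyList(d, list(location = "nucleus"))
  e2 <- build_entity(d2, m)
  expect_identical(e2$children$entityReference$key, ref$key)
  expect_identical(as_census_vec(census(m))[["ProteinReference"]], 2L)
})

test_that("transcription products are RNA for gene targets", {
  out <- build_one("TRANSCRIPTION")
  rx <- out$interaction
  expect_identical(rx$class_name, "TemplateReaction")
  product <- rx$children[[which(names(rx$children) == "product")]]
  expect_identical(product$class_name, "Rna")
  expect_identical(product$children$entityReference$class_name, "RnaReference")
})

test_that("builders refuse the unknown sentinel", {
  r <- parse_line(hand_sig_line("BINDING", 1L), "sig")[[1]]
  expect_error(build_interaction(r, "UNKNOWN", bpx_model()),
               class = "flat2biopax_value_error")
})
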