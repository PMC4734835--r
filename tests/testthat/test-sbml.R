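# Small SBML files are built as text in the tests themselves.

sbml2_minimal <- function(rev = "true", lower = NULL, extra_species = NULL,
                          species_refs = NULL) {
  refs <- species_refs %||% c("M_a_c", "M_b_c")
  c('<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">',
    '<model id="mini" name="mini model">',
    '<listOfCompartments><compartment id="c"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="M_a_c" name="alpha" compartment="c" charge="0"/>',
    '<species id="M_b_c" name="beta" compartment="c" charge="0"/>',
    extra_species,
    '</listOfSpecies>',
    '<listOfReactions>',
    paste0('<reaction id="R_r1" reversible="', rev, '">'),
    '<listOfReactants>',
    paste0('<speciesReference species="', refs[1],
           '" stoichiometry="1"/>'),
    '</listOfReactants><listOfProducts>',
    paste0('<speciesReference species="', refs[2],
           '" stoichiometry="1"/>'),
    '</listOfProducts>',
    if (!is.null(lower)) c(
      '<kineticLaw><listOfParameters>',
      paste0('<parameter id="LOWER_BOUND" value="', lower, '"/>'),
      '<parameter id="UPPER_BOUND" value="1000"/>',
      '</listOfParameters></kineticLaw>'),
    '</reaction>',
    '</listOfReactions></model></sbml>')
}

write_sbml_fixture <- function(lines) {
  f <- withr::local_tempfile(fileext = ".xml",
                             .local_envir = parent.frame())
  writeLines(unlist(lines), f)
  f
}

test_that("a minimal level-2 file imports cleanly in both modes", {
  f <- write_sbml_fixture(sbml2_minimal())
  for (mode in c("strict", "lax")) {
    res <- import_sbml(f, mode)
    expect_equal(length(res$report$repairs), 0, info = mode)
    expect_equal(names(res$model$reactions), "r1")
    expect_equal(render_equation(res$model$reactions$r1$equation),
                 "[c]: a <==> b")
    expect_equal(res$model$compounds$a$name, "alpha")
    expect_equal(res$model$reactions$r1$extra$sbml_id, "R_r1")
  }
})

test_that("level-1 decimal stoichiometry errors strictly, repairs laxly", {
  lvl1 <- c('<?xml version="1.0"?>',
            '<sbml xmlns="http://www.sbml.org/sbml/level1" level="1" version="2">',
            '<model name="m1"><listOfSpecies>',
            '<specie name="M_a_c" compartment="c"/>',
            '<specie name="M_b_c" compartment="c"/>',
            '</listOfSpecies><listOfReactions>',
            '<reaction name="R_r1" reversible="false"><listOfReactants>',
            '<specieReference specie="M_a_c" stoichiometry="1"/>',
            '</listOfReactants><listOfProducts>',
            '<specieReference specie="M_b_c" stoichiometry="1"/>',
            '</listOfProducts></reaction>',
            '</listOfReactions></model></sbml>')
  f_ok <- write_sbml_fixture(lvl1)
  expect_equal(length(import_sbml(f_ok, "strict")$report$repairs), 0)
  bad <- sub('specie="M_a_c" stoichiometry="1"',
             'specie="M_a_c" stoichiometry="0.5"', lvl1)
  f_bad <- write_sbml_fixture(bad)
  expect_error(import_sbml(f_bad, "strict"), "decimal")
  res <- import_sbml(f_bad, "lax")
  expect_equal(res$report$repairs, "decimal_stoichiometry")
  expect_equal(res$model$reactions$r1$equation$left$coef, 0.5)
})

test_that("irreversible reactions keep a conflicting COBRA lower bound", {
  f <- write_sbml_fixture(sbml2_minimal(rev = "false", lower = -1000))
  expect_error(import_sbml(f, "strict"), "LOWER_BOUND")
  res <- import_sbml(f, "lax")
  expect_true("reversibility_conflict" %in% res$report$repairs)
  expect_equal(gemflux:::model_bounds(res$model, "r1"), c(-1000, 1000))
})

test_that("the boundary id suffix creates an exchange reaction laxly", {
  lines <- sbml2_minimal(
    extra_species = '<species id="M_x_b" compartment="c"/>',
    species_refs = c("M_a_c", "M_x_b"))
  f <- write_sbml_fixture(lines)
  expect_error(import_sbml(f, "strict"), "boundary")
  res <- import_sbml(f, "lax")
  expect_true("boundary_suffix" %in% res$report$repairs)
  ex <- grep("^EX_", names(res$model$reactions), value = TRUE)
  expect_equal(length(ex), 1)
})

test_that("undefined species references are dropped laxly with a warning", {
  lines <- sbml2_minimal(species_refs = c("M_a_c", "M_ghost_c"))
  f <- write_sbml_fixture(lines)
  expect_error(import_sbml(f, "strict"), "undefined")
  res <- import_sbml(f, "lax")
  expect_true("undefined_species" %in% res$report$repairs)
  expect_equal(nrow(res$model$reactions$r1$equation$right), 0)
})

test_that("boundaryCondition species drop out of the matrix", {
  lines <- sbml2_minimal(
    extra_species = paste0('<species id="M_ext_c" compartment="c" ',
                           'boundaryCondition="true"/>'),
    species_refs = c("M_ext_c", "M_b_c"))
  f <- write_sbml_fixture(lines)
  res <- import_sbml(f, "strict")
  expect_equal(length(res$report$repairs), 0)
  mv <- matrix_view(res$model)
  expect_false(any(grepl("^ext", mv$compounds)))
  expect_true("b[c]" %in% mv$compounds)
})

test_that("SBML export round-trips through a strict re-import", {
  for (kind in c("chain", "branched", "random")) {
    m <- make_fixture(kind, seed = 17)
    f <- withr::local_tempfile(fileext = ".xml")
    export_sbml(m, f)
    res <- import_sbml(f, "strict")
    expect_equal(length(res$report$repairs), 0, info = kind)
    m2 <- res$model
    mv1 <- matrix_view(m)
    mv2 <- matrix_view(m2)
    expect_setequal(mv2$compounds, mv1$compounds)
    expect_setequal(mv2$reactions, mv1$reactions)
    for (rid in mv1$reactions) {
      expect_equal(as.numeric(mv2$S[mv1$compounds, rid]),
                   as.numeric(mv1$S[, rid]), info = paste(kind, rid))
      expect_equal(unname(gemflux:::model_bounds(m2, rid)),
                   unname(gemflux:::model_bounds(m, rid)),
                   info = paste(kind, rid))
    }
    expect_equal(m2$biomass, m$biomass, info = kind)
  }
})

test_that("objective coefficients and biomass ids drive detection", {
  m <- gem_model(reactions = list(reaction_entry("R_BIO", "A =>"),
                                  reaction_entry("r2", "B => A")))
  expect_equal(detect_biomass(m, c(R_BIO = 1)), "R_BIO")
  m2 <- gem_model(reactions = list(
    reaction_entry("R_biomass_core", "A =>"),
    reaction_entry("r2", "B => A")))
  expect_equal(detect_biomass(m2), "R_biomass_core")
  m3 <- gem_model(reactions = list(reaction_entry("r1", "A =>")))
  expect_null(detect_biomass(m3))
  # ties resolve to the first in model order, with a warning
  m4 <- gem_model(reactions = list(
    reaction_entry("biomass_a", "A =>"),
    reaction_entry("biomass_b", "B =>")))
  expect_warning(pick <- detect_biomass(m4), "multiple")
  expect_equal(pick, "biomass_a")
})

test_that("malformed XML is an import error", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><model>", f)
  expect_error(import_sbml(f), "malformed XML")
})
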