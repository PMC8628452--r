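test_that("toy model satisfies the structural invariants", {
  m <- generate_toy_model(seed = 1)
  expect_equal(nrow(m$reactions), 4)
  expect_equal(nrow(m$metabolites), 3)
  expect_identical(sort(m$genes), c("g1", "gT"))
  expect_equal(m$reactions$id[is_exchange_reaction(m)],
               c("EX_A", "BIOMASS"))
  expect_silent(validate_model(m))
})

test_that("validation catches broken models", {
  m <- generate_toy_model(seed = 1)
  bad <- m; bad$reactions$lower_bound[2] <- 2000
  expect_error(validate_model(bad), "lower_bound > upper_bound")
  bad2 <- m; bad2$stoich$T_A <- c(A_ext = -1, GHOST = 1)
  expect_error(validate_model(bad2), "undeclared metabolite")
  bad3 <- m; bad3$objective_reaction_id <- "NOPE"
  expect_error(validate_model(bad3), "not in the model")
  bad4 <- m; bad4$genes <- c("gT")
  expect_error(validate_model(bad4), "GPR leaves")
})

test_that("stoichiometric matrix reproduces the reaction chemistry", {
  m <- generate_toy_model(seed = 1)
  S <- stoichiometric_matrix(m)
  expect_equal(dim(S), c(3, 4))
  expect_equal(colnames(S), m$reactions$id)
  # exchange columns have exactly one non-zero entry
  expect_true(all(colSums(S[, is_exchange_reaction(m)] != 0) == 1))
  # conversion column conserves mass within the model
  expect_equal(unname(S[, "T_A"]), c(-1, 1, 0))
  # S v = 0 for any FBA optimum
  fba <- solve_fba(m)
  expect_lt(max(abs(S %*% fba$fluxes)), 1e-6)
})

test_that("JSON round trip preserves the model exactly", {
  m <- generate_toy_model(n_chain = 3, branches = list(c(1, 1)),
                          gpr_pattern = "mixed", seed = 7)
  path <- tempfile(fileext = ".json")
  write_json_model(m, path)
  m2 <- load_json_model(path)
  expect_equal(m2$reactions, m$reactions)
  expect_equal(m2$metabolites, m$metabolites)
  expect_equal(m2$stoich, m$stoich)
  expect_equal(m2$genes, m$genes)
  expect_equal(m2$objective_reaction_id, m$objective_reaction_id)
})

test_that("SBML round trip preserves the model and matches the JSON loader", {
  m <- generate_toy_model(n_chain = 3, branches = list(c(2, 1)),
                          gpr_pattern = "mixed", reversible_fraction = 0.5,
                          seed = 11)
  sb <- tempfile(fileext = ".xml")
  js <- tempfile(fileext = ".json")
  write_sbml_model(m, sb)
  write_json_model(m, js)
  m_sb <- load_sbml_model(sb)
  m_js <- load_json_model(js)
  for (field in c("metabolites", "reactions", "stoich", "genes",
                  "objective_reaction_id")) {
    expect_equal(m_sb[[field]], m[[field]], label = paste("sbml", field))
    expect_equal(m_sb[[field]], m_js[[field]], label = paste("parity", field))
  }
})

test_that("fbc gene associations parse when no notes line exists", {
  m <- generate_toy_model(gpr_pattern = "and-pair", seed = 2)
  sb <- tempfile(fileext = ".xml")
  write_sbml_model(m, sb)
  # strip the notes so only the fbc association tree remains
  txt <- readLines(sb)
  txt <- txt[!grepl("notes|GENE_ASSOCIATION", txt)]
  writeLines(txt, sb)
  m2 <- load_sbml_model(sb)
  node_orig <- parse_gpr(m$reactions$gpr[m$reactions$id == "R1"])
  node_fbc <- parse_gpr(m2$reactions$gpr[m2$reactions$id == "R1"])
  expect_identical(node_fbc, node_orig)
})

test_that("missing bounds default with a warning; bad references error", {
  js <- tempfile(fileext = ".json")
  model_json <- list(
    id = "mini",
    metabolites = list(list(id = "A", compartment = "c")),
    reactions = list(
      list(id = "IN", metabolites = list(A = 1), upper_bound = 10,
           gene_reaction_rule = "", objective_coefficient = 0),
      list(id = "OUT", metabolites = list(A = -1), lower_bound = 0,
           upper_bound = 1000, gene_reaction_rule = "",
           objective_coefficient = 1)
    ),
    genes = list()
  )
  jsonlite::write_json(model_json, js, auto_unbox = TRUE)
  expect_warning(m <- load_json_model(js), "defaults applied")
  expect_equal(m$reactions$lower_bound[1], 0)   # irreversible default

  # reversible flag switches the default lower bound
  model_json$reactions[[1]]$reversible <- TRUE
  jsonlite::write_json(model_json, js, auto_unbox = TRUE)
  expect_warning(m2 <- load_json_model(js), "defaults applied")
  expect_equal(m2$reactions$lower_bound[1], -1000)

  # undeclared metabolite is a parse error naming the reaction
  model_json$reactions[[1]]$metabolites <- list(GHOST = 1)
  jsonlite::write_json(model_json, js, auto_unbox = TRUE)
  expect_error(load_json_model(js), "GHOST")

  # no objective reaction is a parse error
  model_json$reactions[[1]]$metabolites <- list(A = 1)
  model_json$reactions[[2]]$objective_coefficient <- 0
  jsonlite::write_json(model_json, js, auto_unbox = TRUE)
  expect_error(suppressWarnings(load_json_model(js)), "objective")
})

test_that("boundary species of COBRA-style SBML are dropped", {
  # L2-flavoured document: kineticLaw bounds, notes GPR, boundary species
  sb <- tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">',
    '<model id="l2toy">',
    '<listOfSpecies>',
    '<species id="A_b" compartment="e" boundaryCondition="true"/>',
    '<species id="A" compartment="c"/>',
    '</listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="EX_A" reversible="true">',
    '<listOfReactants><speciesReference species="A" stoichiometry="1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="A_b" stoichiometry="1"/></listOfProducts>',
    '<kineticLaw><math/>',
    '<listOfParameters>',
    '<parameter id="LOWER_BOUND" value="-10"/>',
    '<parameter id="UPPER_BOUND" value="1000"/>',
    '<parameter id="OBJECTIVE_COEFFICIENT" value="0"/>',
    '</listOfParameters></kineticLaw>',
    '</reaction>',
    '<reaction id="GROW" reversible="false">',
    '<notes><p>GENE_ASSOCIATION: gA and gB</p></notes>',
    '<listOfReactants><speciesReference species="A"/></listOfReactants>',
    '<kineticLaw><math/>',
    '<listOfParameters>',
    '<parameter id="LOWER_BOUND" value="0"/>',
    '<parameter id="UPPER_BOUND" value="1000"/>',
    '<parameter id="OBJECTIVE_COEFFICIENT" value="1"/>',
    '</listOfParameters></kineticLaw>',
    '</reaction>',
    '</listOfReactions>',
    '</model></sbml>'), sb)
  m <- load_sbml_model(sb)
  expect_equal(m$metabolites$id, "A")            # boundary species dropped
  expect_true(all(is_exchange_reaction(m)))      # both single-metabolite
  expect_equal(m$reactions$lower_bound[m$reactions$id == "EX_A"], -10)
  expect_equal(m$objective_reaction_id, "GROW")
  expect_equal(m$reactions$gpr[m$reactions$id == "GROW"], "gA and gB")
  expect_identical(sort(m$genes), c("gA", "gB"))
})
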