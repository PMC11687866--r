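# Stoichiometric model container, SBML round trip, FBA/FVA/pFBA.

test_that("SBML round trip is lossless and the fixture has 12 reactions", {
  m <- make_toy_network(toy_full_spec())
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, f)
  expect_models_equal(read_sbml(f), m)

  # default fixture: 12 reactions, objective set
  f2 <- withr::local_tempfile(fileext = ".xml")
  write_sbml(make_toy_network(), f2)
  m2 <- read_sbml(f2)
  expect_equal(nrow(m2$rxns), 12)
  expect_identical(m2$objective, list(reaction = "ATPM", direction = "max"))

  # ids with characters outside the SBML SId alphabet survive
  weird <- metabolic_model(
    "w", data.frame(id = "x_e", name = "x", compartment = "e"),
    list(list(id = "EX_x_RPE-PR", stoich = c(x_e = -1),
              lower_bound = -1, upper_bound = 1)))
  f3 <- withr::local_tempfile(fileext = ".xml")
  write_sbml(weird, f3)
  expect_identical(read_sbml(f3)$rxns$id, "EX_x_RPE-PR")
})

test_that("SBML validation rejects malformed input by name", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><model><unclosed></model>", f)
  expect_error(read_sbml(f), "parse error")

  # a reaction without FBC bounds is rejected by id
  f2 <- withr::local_tempfile(fileext = ".xml")
  writeLines(paste0(
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
    'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
    'level="3" version="1" fbc:required="false"><model id="m">',
    '<listOfCompartments><compartment id="c" constant="true"/>',
    '</listOfCompartments>',
    '<listOfSpecies><species id="M_x_c" compartment="c" constant="false" ',
    'boundaryCondition="false" hasOnlySubstanceUnits="false"/>',
    '</listOfSpecies>',
    '<listOfReactions><reaction id="R_NOBOUNDS" reversible="false" ',
    'fast="false"><listOfProducts>',
    '<speciesReference species="M_x_c" stoichiometry="1" constant="true"/>',
    '</listOfProducts></reaction></listOfReactions></model></sbml>'), f2)
  expect_error(read_sbml(f2), "NOBOUNDS")
})

test_that("the SBML writer is readable by an independent SBML/FBC stack", {
  m <- make_toy_network(toy_full_spec())
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, f)
  script <- withr::local_tempfile(fileext = ".py")
  writeLines(c(
    "import sys",
    "import libsbml",
    "doc = libsbml.readSBMLFromFile(sys.argv[1])",
    "bad = sum(doc.getError(i).getSeverity() >= libsbml.LIBSBML_SEV_ERROR",
    "          for i in range(doc.getNumErrors()))",
    "assert bad == 0, 'SBML errors'",
    "model = doc.getModel()",
    "print(model.getNumReactions(), model.getNumSpecies())"), script)
  out <- suppressWarnings(system2("python", c(script, f), stdout = TRUE,
                                  stderr = FALSE))
  expect_equal(scan(text = out[length(out)], quiet = TRUE),
               c(nrow(m$rxns), nrow(m$mets)))
})

test_that("FBA matches the toy closed form and reports infeasibility", {
  m <- make_toy_network()
  # glucose <= 2, O2 <= 12: two glucose fully oxidised at 32 ATP each
  s <- fba(toy_with_bounds(m, 2, 12))
  expect_equal(s$objective_value, 64, tolerance = 1e-9)

  # closed system
  mc <- m
  for (rid in c("EX_glc", "EX_o2", "EX_lac")) {
    mc <- set_bounds(mc, rid, lower = 0, upper = 0)
  }
  sc <- fba(mc)
  expect_equal(sc$objective_value, 0, tolerance = 1e-9)

  # lactate floor above 2x glucose with no other carbon: empty polytope
  expect_identical(fba(toy_with_bounds(m, 1, 0, lac_floor = 3))$status,
                   "infeasible")

  # no objective is a configuration error
  m_noobj <- m
  m_noobj$objective <- NULL
  expect_error(fba(m_noobj), "objective")
})

test_that("FBA equals the closed-form yield over random bound draws", {
  m <- make_toy_network()
  set.seed(101)
  for (i in 1:20) {
    G <- runif(1, 0, 5)
    O <- runif(1, 0, 20)
    L <- runif(1, 0, 2.4 * G)
    sol <- fba(toy_with_bounds(m, G, O, L))
    cf <- toy_closed_form_atp(G, O, L)
    if (is.na(cf)) {
      expect_identical(sol$status, "infeasible")
    } else {
      expect_equal(sol$objective_value, cf, tolerance = 1e-6)
    }
  }
})

test_that("optimal solutions satisfy steady state within tolerance", {
  m <- make_toy_network(toy_full_spec())
  set.seed(7)
  for (i in 1:5) {
    sol <- fba(toy_with_bounds(m, runif(1, 1, 5), runif(1, 1, 20),
                               aa = runif(1, 0, 2)))
    expect_identical(sol$status, "optimal")
    resid <- max(abs(as.numeric(m$S %*% sol$fluxes)))
    expect_lt(resid, 1e-6)
    expect_true(all(sol$fluxes >= m$rxns$lower_bound - 1e-6))
    expect_true(all(sol$fluxes <= m$rxns$upper_bound + 1e-6))
  }
})

test_that("FVA pins the objective, attains free bounds, widens parallel routes", {
  m <- toy_with_bounds(make_toy_network(), 2, 12)
  fv <- fva(m, "ATPM", objective_fraction = 1.0)
  expect_equal(fv$min_flux, fv$max_flux, tolerance = 1e-6)
  expect_equal(fv$max_flux, 64, tolerance = 1e-6)

  # fraction 0: an exchange with bounds (-5, 5) and unconstrained
  # connectivity spans its full range
  m2 <- metabolic_model(
    "tiny",
    data.frame(id = c("x_e", "x_c", "y_c"), name = c("x", "x", "y"),
               compartment = c("e", "c", "c")),
    list(list(id = "EX_x", stoich = c(x_e = -1), lower_bound = -5,
              upper_bound = 5),
         list(id = "T_x", stoich = c(x_e = -1, x_c = 1),
              lower_bound = -1000, upper_bound = 1000),
         list(id = "SK_x", stoich = c(x_c = -1), lower_bound = -1000,
              upper_bound = 1000),
         list(id = "DM_y", stoich = c(y_c = -1), lower_bound = 0,
              upper_bound = 1000)),
    objective = list(reaction = "DM_y", direction = "max"))
  fv2 <- fva(m2, "EX_x", objective_fraction = 0)
  expect_equal(unlist(fv2[, c("min_flux", "max_flux")]),
               c(min_flux = -5, max_flux = 5), tolerance = 1e-6)

  # a duplicated parallel pathway has a strictly wider FVA range than its
  # pFBA flux (the total can route through either copy)
  dup <- add_reactions_from(
    metabolic_model("d", data.frame(id = c("glc_e", "glc_c"),
                                    name = c("glc_e", "glc_c"),
                                    compartment = c("e", "c")),
      list(list(id = "T_glc_b", stoich = c(glc_e = -1, glc_c = 1),
                lower_bound = -1000, upper_bound = 1000))),
    make_toy_network(), make_toy_network()$rxns$id)
  dup <- set_objective(dup, "ATPM", "max")
  dup <- toy_with_bounds(dup, 2, 12)
  fvd <- fva(dup, "T_glc_b", objective_fraction = 1.0)
  pf <- pfba(dup)
  expect_gt(fvd$max_flux - fvd$min_flux,
            abs(pf$fluxes[["T_glc_b"]]) + 1e-6)

  # infeasible base problem propagates
  bad <- toy_with_bounds(make_toy_network(), 1, 0, lac_floor = 3)
  expect_error(fva(bad, "ATPM"), "infeasible")
})

test_that("pFBA attains the FBA optimum with no greater total flux", {
  m <- toy_with_bounds(make_toy_network(toy_full_spec()), 3, 10, 1, aa = 1)
  base <- fba(m)
  p <- pfba(m)
  expect_equal(p$objective_value, base$objective_value,
               tolerance = 1e-6 * max(1, abs(base$objective_value)))
  expect_lte(p$total_flux, sum(abs(base$fluxes)) + 1e-6)

  # closed system: the parsimonious solution is the zero vector
  mc <- make_toy_network()
  for (rid in c("EX_glc", "EX_o2", "EX_lac")) {
    mc <- set_bounds(mc, rid, lower = 0, upper = 0)
  }
  expect_equal(max(abs(pfba(mc)$fluxes)), 0, tolerance = 1e-9)

  # with two equivalent lactate-export routes, pFBA uses only one
  dup <- add_reactions_from(
    metabolic_model("d", data.frame(id = c("lac_c", "lac_e"),
                                    name = c("lac_c", "lac_e"),
                                    compartment = c("c", "e")),
      list(list(id = "T_lac_b", stoich = c(lac_c = -1, lac_e = 1),
                lower_bound = -1000, upper_bound = 1000))),
    make_toy_network(), make_toy_network()$rxns$id)
  dup <- set_objective(dup, "ATPM", "max")
  dup <- toy_with_bounds(dup, 2, 0, lac_floor = 4)
  p2 <- pfba(dup)
  used <- sum(abs(p2$fluxes[c("T_lac", "T_lac_b")]) > 1e-8)
  expect_equal(used, 1)
})

test_that("loop check flags a constructed two-reaction cycle", {
  m <- make_toy_network()
  # add a second transporter to create an internal glc_e/glc_c cycle
  dup <- add_reactions_from(
    metabolic_model("d", data.frame(id = c("glc_e", "glc_c"),
                                    name = c("glc_e", "glc_c"),
                                    compartment = c("e", "c")),
      list(list(id = "T_glc_b", stoich = c(glc_e = -1, glc_c = 1),
                lower_bound = -1000, upper_bound = 1000))),
    m, m$rxns$id)
  sol <- fba(toy_with_bounds(set_objective(dup, "ATPM", "max"), 2, 12))
  # graft a circulating component onto the solution
  looped <- sol
  looped$fluxes[c("T_glc", "T_glc_b")] <-
    looped$fluxes[c("T_glc", "T_glc_b")] + c(50, -50)
  expect_true(loop_check(dup, looped)$has_loop)
  expect_false(loop_check(dup, pfba(toy_with_bounds(
    set_objective(dup, "ATPM", "max"), 2, 12)))$has_loop)
})

test_that("model construction enforces the declared invariants", {
  mets <- data.frame(id = c("a_c", "b_c"), name = c("a", "b"),
                     compartment = "c")
  expect_error(metabolic_model("m", mets, list(
    list(id = "r", stoich = c(missing_met = 1),
         lower_bound = 0, upper_bound = 1))), "unknown metabolites")
  expect_error(metabolic_model("m", mets, list(
    list(id = "r", stoich = c(a_c = 1), lower_bound = 2,
         upper_bound = 1))), "lower_bound")
  expect_error(metabolic_model("m", rbind(mets, mets[1, ]), list(
    list(id = "r", stoich = c(a_c = 1), lower_bound = 0,
         upper_bound = 1))), "duplicate")
})

test_that("flux tables export as TSV with bounds", {
  m <- toy_with_bounds(make_toy_network(), 2, 12)
  sol <- pfba(m)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_flux_tsv(sol, m, f)
  tab <- read.delim(f)
  expect_identical(names(tab),
                   c("reaction_id", "flux", "lower_bound", "upper_bound"))
  expect_equal(tab$flux[tab$reaction_id == "ATPM"], 64, tolerance = 1e-6)
})
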