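# Expression discretization, GPR scoring, CORDA-style extraction.

test_that("discretization follows the five-category rule", {
  p <- expression_profile("RPE", c(g1 = 1, g2 = 2, g3 = 3, g4 = 4, g5 = 100))
  d <- discretize(p)
  expect_identical(as.character(d$gene_conf[c("g1", "g3", "g5")]),
                   c("LOW", "MEDIUM", "HIGH"))

  p2 <- expression_profile("rod", c(a = 1e-6, b = NA, c = 1, d = 2, e = 3,
                                    f = 4, g = 5))
  d2 <- discretize(p2)
  expect_identical(as.character(d2$gene_conf["a"]), "NOT_PRESENT")
  expect_identical(as.character(d2$gene_conf["b"]), "UNKNOWN")

  expect_error(discretize(expression_profile("x", c(a = NA_real_, b = NA))),
               "no expressed genes")
})

test_that("discretization category counts and monotonicity hold at scale", {
  set.seed(3)
  v <- stats::setNames(rlnorm(1000) + 1e-4, sprintf("g%04d", 1:1000))
  d <- discretize(expression_profile("RPE", v))
  counts <- table(d$gene_conf)
  expect_lte(abs(counts[["LOW"]] - 250), 1)
  expect_lte(abs(counts[["HIGH"]] - 250), 1)
  expect_lte(abs(counts[["MEDIUM"]] - 500), 2)

  # raising one gene's value never lowers its category
  rank_of <- function(cat) match(cat, c("NOT_PRESENT", "LOW", "MEDIUM", "HIGH"))
  for (g in sample(names(v), 10)) {
    v2 <- v
    v2[g] <- v2[g] * 4
    d2 <- discretize(expression_profile("RPE", v2))
    expect_gte(rank_of(as.character(d2$gene_conf[g])),
               rank_of(as.character(d$gene_conf[g])))
  }
})

test_that("GPR scoring combines confidences as complexes and isoenzymes", {
  m <- metabolic_model(
    "g", data.frame(id = "x_c", name = "x", compartment = "c"),
    list(list(id = "r_and", stoich = c(x_c = 1), lower_bound = 0,
              upper_bound = 1, gpr = "gA and gB"),
         list(id = "r_or", stoich = c(x_c = 1), lower_bound = 0,
              upper_bound = 1, gpr = "gC or gD"),
         list(id = "r_nested", stoich = c(x_c = 1), lower_bound = 0,
              upper_bound = 1, gpr = "(gA and gU) or gB"),
         list(id = "r_none", stoich = c(x_c = 1), lower_bound = 0,
              upper_bound = 1),
         list(id = "r_unres", stoich = c(x_c = 1), lower_bound = 0,
              upper_bound = 1, gpr = "gZ")))
  conf <- conf_from(c(gA = "HIGH", gB = "LOW", gC = "NOT_PRESENT",
                      gD = "MEDIUM", gU = "UNKNOWN"))
  conf <- score_reactions(m, conf)
  rc <- as.character(conf$rxn_conf)
  names(rc) <- names(conf$rxn_conf)
  expect_identical(unname(rc[c("r_and", "r_or", "r_nested", "r_none",
                               "r_unres")]),
                   c("LOW", "MEDIUM", "LOW", "UNKNOWN", "UNKNOWN"))
})

test_that("malformed GPR expressions are rejected with the reaction id", {
  m <- metabolic_model(
    "g", data.frame(id = "x_c", name = "x", compartment = "c"),
    list(list(id = "r_ok", stoich = c(x_c = 1), lower_bound = 0,
              upper_bound = 1)))
  m$rxns$gpr[1] <- "gA and (gB or"  # bypass constructor canonicalisation
  expect_error(score_reactions(m, conf_from(c(gA = "HIGH"))), "r_ok")
})

test_that("extraction keeps HIGH support, prunes silent routes, keeps biomass", {
  template <- make_toy_network(toy_full_spec())

  # all reactions HIGH: output is a flux-consistent subset
  genes <- unique(unlist(lapply(template$rxns$gpr,
                                function(g) gpr_genes(gpr_parse(g)))))
  all_high <- score_reactions(template, conf_from(
    stats::setNames(rep("HIGH", length(genes)), genes)))
  sub <- extract_cell_model(template, all_high, "BIOMASS")
  expect_true(all(sub$rxns$id %in% template$rxns$id))
  expect_gt(fba(set_objective(sub, "BIOMASS", "max"))$objective_value, 0)

  # parallel HIGH and NOT_PRESENT routes to lactate: silent route removed
  conf2 <- score_reactions(template, conf_from(stats::setNames(
    ifelse(genes %in% c("gTfa", "gFAOX"), "NOT_PRESENT", "HIGH"), genes)))
  sub2 <- extract_cell_model(template, conf2, "BIOMASS")
  expect_false(any(c("FAOX", "T_fa") %in% sub2$rxns$id))
  expect_length(attr(sub2, "forced_low_confidence"), 0)

  # biomass infeasible template is rejected
  dead <- set_bounds(template, "EX_glc", lower = 0, upper = 0)
  dead <- set_bounds(dead, "EX_aa", lower = 0, upper = 0)
  expect_error(extract_cell_model(dead, all_high, "BIOMASS"),
               "cannot produce biomass")
  expect_error(extract_cell_model(template, all_high, "NO_SUCH"),
               "not in template")
})

test_that("an indispensable NOT_PRESENT reaction is retained and flagged", {
  # six-reaction chain: biomass depends on T_x with no alternative
  m <- metabolic_model(
    "chain",
    data.frame(id = c("x_e", "x_c", "b_c"), name = c("x", "x", "b"),
               compartment = c("e", "c", "c")),
    list(list(id = "EX_x", stoich = c(x_e = -1), lower_bound = -10,
              upper_bound = 10),
         list(id = "T_x", stoich = c(x_e = -1, x_c = 1), lower_bound = -10,
              upper_bound = 10, gpr = "gT"),
         list(id = "CONV", stoich = c(x_c = -1, b_c = 1), lower_bound = 0,
              upper_bound = 10, gpr = "gC"),
         list(id = "ALT", stoich = c(x_c = -1, b_c = 1), lower_bound = 0,
              upper_bound = 10, gpr = "gAlt"),
         list(id = "BIO", stoich = c(b_c = -1), lower_bound = 0,
              upper_bound = 10, gpr = "gB"),
         list(id = "DM_x", stoich = c(x_c = -1), lower_bound = 0,
              upper_bound = 10)))
  conf <- score_reactions(m, conf_from(c(gT = "NOT_PRESENT", gC = "HIGH",
                                         gAlt = "NOT_PRESENT", gB = "HIGH")))
  sub <- extract_cell_model(m, conf, "BIO")
  # exhaustive check: every subset containing BIO but not T_x is dead
  expect_true("T_x" %in% sub$rxns$id)
  expect_true("T_x" %in% attr(sub, "forced_low_confidence"))
  # the NOT_PRESENT route with an HIGH alternative is dropped
  expect_false("ALT" %in% sub$rxns$id)
})

test_that("restore_mandatory adds back lost reactions idempotently", {
  template <- make_toy_network(toy_full_spec())
  genes <- unique(unlist(lapply(template$rxns$gpr,
                                function(g) gpr_genes(gpr_parse(g)))))
  conf <- score_reactions(template, conf_from(
    stats::setNames(rep("HIGH", length(genes)), genes)))
  sub <- extract_cell_model(template, conf, "BIOMASS")
  mandatory <- c("ATPM", exchange_reactions(template)$reaction)

  restored <- restore_mandatory(sub, template, mandatory)
  expect_true(all(mandatory %in% restored$rxns$id))
  # template's exchange set is a subset of the restored exchange set
  expect_true(all(exchange_reactions(template)$reaction %in%
                    exchange_reactions(restored)$reaction))
  # idempotent
  again <- restore_mandatory(restored, template, mandatory)
  expect_identical(again$rxns$id, restored$rxns$id)
  # unknown mandatory id names the offender
  expect_error(restore_mandatory(sub, template, "GHOST"), "GHOST")
})

test_that("TSV expression input handles blanks and symbol mapping", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tvalue", "SYM1\t2.5", "SYM2\t", "SYM3\t0.1"), f)
  mapping <- data.frame(symbol = c("SYM1", "SYM2"),
                        gene_id = c("ENSG1", "ENSG2"))
  expect_message(p <- read_expression_tsv(f, "RPE", mapping), "not in mapping")
  expect_setequal(names(p$values), c("ENSG1", "ENSG2"))
  expect_true(is.na(p$values[["ENSG2"]]))
})
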