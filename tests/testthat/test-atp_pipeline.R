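# Maximal ATP yield and the parameter sweeps.

coupled_toy <- function() {
  m <- make_toy_network(toy_full_spec())
  couple(m, m)
}

test_that("constrained yields match the vertex-enumeration oracle", {
  cp <- coupled_toy()
  cs0 <- build_constraint_set("perifovea", "dark", amino_acids = TRUE)
  plasma <- read_plasma_table()
  aa_ratio <- sum(plasma[setdiff(names(plasma), "glucose")]) /
    plasma[["glucose"]]
  set.seed(23)
  for (i in 1:20) {
    cs <- cs0
    G <- runif(1, 0.5, 5)
    L <- runif(1, 0, 2.2 * G)
    O <- runif(1, 0.5, 6)
    b <- cs$bounds
    b$uptake_max[b$metabolite == "glucose" & b$interface == "e_RPE"] <- G
    b$export_min[b$metabolite == "lactate"] <- L
    o2sel <- b$metabolite == "oxygen"
    b$uptake_max[o2sel] <- O * b$uptake_max[o2sel] / sum(b$uptake_max[o2sel])
    cs$bounds <- b
    r <- max_atp(cp, cs)
    A <- sum(b$uptake_max[!b$metabolite %in%
                            c("oxygen", "glucose", "lactate", "water")])
    oracle <- toy_vertex_oracle(G, O, L, A = A)
    if (is.na(oracle)) {
      expect_identical(r$status, "INFEASIBLE")
    } else {
      expect_equal(r$atp_yield, oracle, tolerance = 1e-6)
    }
  }
})

test_that("light with glucose only is infeasible; amino acids restore it", {
  cp <- coupled_toy()
  r <- max_atp(cp, build_constraint_set("perifovea", "light"))
  expect_identical(r$status, "INFEASIBLE")
  r2 <- max_atp(cp, build_constraint_set("perifovea", "light",
                                         amino_acids = TRUE))
  expect_identical(r2$status, "optimal")
  expect_gt(r2$atp_yield, 0)
  # the objective reaction must exist
  expect_error(max_atp(cp, build_constraint_set("perifovea", "dark"),
                       objective = "MISSING"), "MISSING")
})

test_that("amino-acid sweep is monotone with a feasibility threshold in light", {
  cp <- coupled_toy()
  sw <- sweep_amino_acids(cp, build_constraint_set("perifovea", "light",
                                                   amino_acids = TRUE))
  expect_identical(sw$status[sw$multiplier == 0.25], "INFEASIBLE")
  expect_identical(sw$status[sw$multiplier == 0.5], "optimal")
  y <- sw$atp_yield
  feas <- !is.na(y)
  expect_true(all(diff(y[feas]) >= -1e-9))
  expect_equal(attr(sw, "threshold"), 0.5)

  # doubling beyond saturation changes the yield only marginally
  swd <- sweep_amino_acids(cp, build_constraint_set("perifovea", "dark",
                                                    amino_acids = TRUE))
  y1 <- swd$atp_yield[swd$multiplier == 1]
  y2 <- swd$atp_yield[swd$multiplier == 2]
  expect_lt(y2 - y1, 1e-6)
  expect_error(sweep_amino_acids(cp, build_constraint_set("perifovea", "dark")),
               "disabled")
})

test_that("feasibility thresholds sit on the closed-form boundary", {
  cp <- coupled_toy()
  cs <- build_constraint_set("perifovea", "dark")
  G <- 4.6
  L <- 8.2
  # glucose decreasing on the 0.10 grid: infeasible below L/2
  th <- feasibility_threshold(cp, cs, "glucose", "decrease_uptake")
  grid_vals <- seq(G, 0, by = -0.1)
  expected <- min(grid_vals[grid_vals >= L / 2 - 1e-9])
  expect_equal(th$threshold, expected, tolerance = 1e-9)
  expect_false(th$open_boundary)

  # lactate increasing: infeasible above 2 G
  th2 <- feasibility_threshold(cp, cs, "lactate", "increase_export")
  grid2 <- L + 0.1 * (0:200)
  expect_equal(th2$threshold, max(grid2[grid2 <= 2 * G + 1e-9]),
               tolerance = 1e-9)

  # reproducible: identical grids and decisions across runs
  th3 <- feasibility_threshold(cp, cs, "glucose", "decrease_uptake")
  expect_identical(th, th3)

  # step larger than the feasible window: boundary flagged open
  cs_easy <- cs
  cs_easy$bounds$export_min[cs_easy$bounds$metabolite == "lactate"] <- 0
  th4 <- feasibility_threshold(cp, cs_easy, "glucose", "decrease_uptake",
                               step = 50)
  expect_true(th4$open_boundary)
})

test_that("lipid pools add yield only up to spare oxygen and then plateau", {
  cp <- coupled_toy()
  cs <- build_constraint_set("perifovea", "dark")
  lp <- lipid_pool_test(cp, cs, bound = 1.0)
  expect_gte(lp$delta, 0)
  # gain is bounded by spare oxygen at the fatty-acid ATP-per-O2 yield
  o2_total <- 3.18 + 0.30 + 0.56
  spare <- o2_total - 6 * (4.6 - 8.2 / 2)
  expect_lte(lp$delta, 106 / 23 * spare + 1e-6)
  # plateau: a larger pool bound changes nothing once oxygen saturates
  lp2 <- lipid_pool_test(cp, cs, bound = 5.0)
  expect_equal(lp2$delta, lp$delta, tolerance = 1e-6)
  # bound 0 is a no-op
  lp0 <- lipid_pool_test(cp, cs, bound = 0)
  expect_equal(lp0$delta, 0, tolerance = 1e-9)
  expect_warning(lipid_pool_test(cp, cs, pool_reactions = "EX_ghost"),
                 "EX_ghost")
})

test_that("relaxing a bound never lowers the maximal yield", {
  cp <- coupled_toy()
  cs <- build_constraint_set("perifovea", "dark", amino_acids = TRUE)
  base <- max_atp(cp, cs)$atp_yield
  set.seed(31)
  for (i in 1:8) {
    cs2 <- cs
    b <- cs2$bounds
    if (runif(1) < 0.5) {
      j <- sample(which(b$uptake_max > 0 & is.finite(b$uptake_max)), 1)
      b$uptake_max[j] <- b$uptake_max[j] * (1 + runif(1, 0, 1))
    } else {
      j <- which(b$export_min > 0)
      b$export_min[j] <- b$export_min[j] * runif(1, 0.3, 1)
    }
    cs2$bounds <- b
    y <- max_atp(cp, cs2)$atp_yield
    expect_gte(y, base - 1e-8)
  }
})

test_that("the full grid reproduces the qualitative yield pattern", {
  models <- toy_cell_models()
  grid <- run_grid(models)
  expect_equal(nrow(grid), 16)

  # without amino acids, light cells are infeasible everywhere
  noaa_light <- grid[!grid$amino_acids & grid$condition == "light", ]
  expect_true(all(noaa_light$status == "INFEASIBLE"))

  # dark yield exceeds light yield at both sites (amino acids enabled)
  aa <- grid[grid$amino_acids, ]
  for (tag in unique(aa$model_tag)) {
    for (site in unique(aa$site)) {
      dk <- aa$atp_yield[aa$model_tag == tag & aa$site == site &
                           aa$condition == "dark"]
      lt <- aa$atp_yield[aa$model_tag == tag & aa$site == site &
                           aa$condition == "light"]
      expect_gt(dk, lt)
    }
  }

  # amino-acid inclusion in the dark adds a positive increment
  for (site in c("perifovea", "fovea")) {
    y0 <- grid$atp_yield[grid$model_tag == "control" & grid$site == site &
                           grid$condition == "dark" & !grid$amino_acids]
    y1 <- grid$atp_yield[grid$model_tag == "control" & grid$site == site &
                           grid$condition == "dark" & grid$amino_acids]
    expect_gt(y1, y0)
  }

  # a failing cell is recorded, not fatal
  broken <- c(models, list(bad = "not a model"))
  g2 <- run_grid(broken, sites = "perifovea", conditions = "dark",
                 amino_acids = FALSE)
  expect_identical(g2$status[g2$model_tag == "bad"], "error")
  expect_identical(g2$status[g2$model_tag == "control"], "optimal")
})

test_that("grid runs are deterministic: identical manifests across runs", {
  g1 <- run_grid(toy_cell_models(), sites = "perifovea")
  g2 <- run_grid(toy_cell_models(), sites = "perifovea")
  m1 <- run_manifest(g1)
  m2 <- run_manifest(g2)
  expect_identical(m1$results_hash, m2$results_hash)
  expect_identical(m1$config_hash, m2$config_hash)

  f <- withr::local_tempfile(fileext = ".tsv")
  write_grid_tsv(g1, f)
  expect_equal(nrow(read.delim(f)), nrow(g1))
  fm <- withr::local_tempfile(fileext = ".json")
  write_manifest(m1, fm)
  expect_identical(jsonlite::read_json(fm)$results_hash, m1$results_hash)
})
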