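# Synthetic-data generators: a toy metabolic network with closed-form
# maximal ATP yields, expression profiles with planted category structure,
# and aging tables built from a known calibration and density curve. Every
# generator is a pure function of its spec and seed.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Specification of the toy metabolic network
#'
#' A minimal single-cell network with the pathway structure that matters
#' for outer-retina energetics: glycolysis to lactate, full glucose
#' oxidation, optional amino-acid and fatty-acid oxidation routes, an ATP
#' hydrolysis demand and an optional biomass sink. Whole-number yields keep
#' the closed-form maximal ATP yield exact in rational arithmetic.
#'
#' The amino-acid route models an alanine-like substrate: it can be
#' oxidised (for ATP, using oxygen) or converted to lactate (supplying the
#' lactate export floor without oxygen). Per unit oxygen the toy yields are
#' glucose 32/6, amino acid 15/3, fatty acid 106/23, so glucose oxidation
#' is always the preferred oxygen sink.
#'
#' @param atp_per_glucose_oxidation total ATP per fully oxidised glucose
#'   (default 32).
#' @param atp_per_glucose_glycolysis ATP per glucose converted to lactate
#'   (default 2).
#' @param o2_per_glucose oxygen per fully oxidised glucose (default 6).
#' @param amino_acids logical; include the amino-acid route.
#' @param atp_per_aa,o2_per_aa amino-acid oxidation yields (15 ATP, 3 O2).
#' @param fatty_acids logical; include the fatty-acid route.
#' @param atp_per_fa,o2_per_fa fatty-acid oxidation yields (106 ATP, 23 O2).
#' @param biomass logical; include a biomass sink reaction.
#' @return a `toy_network_spec`.
#' @export
toy_network_spec <- function(atp_per_glucose_oxidation = 32,
                             atp_per_glucose_glycolysis = 2,
                             o2_per_glucose = 6,
                             amino_acids = FALSE, atp_per_aa = 15,
                             o2_per_aa = 3,
                             fatty_acids = FALSE, atp_per_fa = 106,
                             o2_per_fa = 23,
                             biomass = TRUE) {
  vals <- c(atp_per_glucose_oxidation, atp_per_glucose_glycolysis,
            o2_per_glucose, atp_per_aa, o2_per_aa, atp_per_fa, o2_per_fa)
  if (any(vals <= 0) || any(abs(vals - round(vals)) > 1e-9)) {
    stop("toy network yields must be positive integers")
  }
  if (atp_per_glucose_oxidation <= atp_per_glucose_glycolysis) {
    stop("oxidation must out-yield glycolysis")
  }
  structure(list(atp_per_glucose_oxidation = atp_per_glucose_oxidation,
                 atp_per_glucose_glycolysis = atp_per_glucose_glycolysis,
                 o2_per_glucose = o2_per_glucose,
                 amino_acids = amino_acids, atp_per_aa = atp_per_aa,
                 o2_per_aa = o2_per_aa,
                 fatty_acids = fatty_acids, atp_per_fa = atp_per_fa,
                 o2_per_fa = o2_per_fa, biomass = biomass),
            class = "toy_network_spec")
}

#' Build the toy metabolic network
#'
#' Compartments `c` (cytosol) and `e` (extracellular). Exchanges follow the
#' export-positive sign convention; transporters are reversible. CO2 leaves
#' through a cytosolic demand and water through a reversible cytosolic
#' sink, so the extracellular boundary carries only circulation-relevant
#' species. The objective is the ATP hydrolysis demand `ATPM`.
#'
#' @param spec a [toy_network_spec()].
#' @param id model id.
#' @return a `metabolic_model` (12 reactions for the default spec).
#' @export
make_toy_network <- function(spec = toy_network_spec(), id = "toy") {
  stopifnot(inherits(spec, "toy_network_spec"))
  met <- function(i, comp) data.frame(id = i, name = i, compartment = comp,
                                      stringsAsFactors = FALSE)
  mets <- rbind(
    met("glc_e", "e"), met("glc_c", "c"),
    met("o2_e", "e"), met("o2_c", "c"),
    met("lac_e", "e"), met("lac_c", "c"),
    met("co2_c", "c"), met("h2o_c", "c"),
    met("atp_c", "c"), met("adp_c", "c"), met("pi_c", "c"))

  rxn <- function(id, stoich, lb = 0, ub = 1000, gpr = "") {
    list(id = id, stoich = stoich, lower_bound = lb, upper_bound = ub,
         gpr = gpr)
  }
  yo <- spec$atp_per_glucose_oxidation
  yg <- spec$atp_per_glucose_glycolysis
  no <- spec$o2_per_glucose
  reactions <- list(
    rxn("EX_glc", c(glc_e = -1), lb = -1000),
    rxn("EX_o2", c(o2_e = -1), lb = -1000),
    rxn("EX_lac", c(lac_e = -1), lb = -1000),
    rxn("T_glc", c(glc_e = -1, glc_c = 1), lb = -1000, gpr = "gTglc"),
    rxn("T_o2", c(o2_e = -1, o2_c = 1), lb = -1000, gpr = "gTo2"),
    rxn("T_lac", c(lac_c = -1, lac_e = 1), lb = -1000, gpr = "gTlac"),
    rxn("GLYC", c(glc_c = -1, adp_c = -yg, pi_c = -yg,
                  lac_c = 2, atp_c = yg, h2o_c = yg),
        gpr = "gGLYC1 and gGLYC2"),
    rxn("OX", c(glc_c = -1, o2_c = -no, adp_c = -yo, pi_c = -yo,
                co2_c = no, atp_c = yo, h2o_c = yo + no),
        gpr = "gOX1 or gOX2"),
    rxn("ATPM", c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1)),
    rxn("DM_co2", c(co2_c = -1)),
    rxn("SK_h2o", c(h2o_c = -1), lb = -1000))

  if (spec$amino_acids) {
    mets <- rbind(mets, met("aa_e", "e"), met("aa_c", "c"))
    ya <- spec$atp_per_aa; na <- spec$o2_per_aa
    reactions <- c(reactions, list(
      rxn("EX_aa", c(aa_e = -1), lb = -1000),
      rxn("T_aa", c(aa_e = -1, aa_c = 1), lb = -1000, gpr = "gTaa"),
      rxn("AAOX", c(aa_c = -1, o2_c = -na, adp_c = -ya, pi_c = -ya,
                    co2_c = na, atp_c = ya, h2o_c = ya + na),
          gpr = "gAAOX"),
      rxn("AALAC", c(aa_c = -1, lac_c = 1), gpr = "gAALAC")))
  }
  if (spec$fatty_acids) {
    mets <- rbind(mets, met("fa_e", "e"), met("fa_c", "c"))
    yf <- spec$atp_per_fa; nf <- spec$o2_per_fa
    reactions <- c(reactions, list(
      rxn("EX_fa", c(fa_e = -1), lb = 0),  # closed until a run opens it
      rxn("T_fa", c(fa_e = -1, fa_c = 1), lb = -1000, gpr = "gTfa"),
      rxn("FAOX", c(fa_c = -1, o2_c = -nf, adp_c = -yf, pi_c = -yf,
                    co2_c = 16, atp_c = yf, h2o_c = yf + nf),
          gpr = "gFAOX")))
  }
  if (spec$biomass) {
    # biomass is a sink on its precursors: macromolecule mass leaves the
    # balanced system, as in genome-scale biomass equations
    bm <- c(glc_c = -0.1, atp_c = -2, h2o_c = -2, adp_c = 2, pi_c = 2)
    if (spec$amino_acids) bm <- c(bm, aa_c = -0.05)
    reactions <- c(reactions, list(rxn("BIOMASS", bm)))
  }

  m <- metabolic_model(id, mets, reactions,
                       objective = list(reaction = "ATPM", direction = "max"))
  attr(m, "toy_spec") <- spec
  m
}

#' Closed-form maximal ATP yield of the glucose-only toy network
#'
#' With glucose uptake bound `G`, oxygen uptake bound `O` and lactate
#' export floor `L`, the LP optimum has the closed form
#' `ATP* = Y_ox * g_ox + Y_gly * (G - g_ox)` with
#' `g_ox = min(G - L/2, O / o2_per_glucose)` (all remaining glucose runs
#' through glycolysis, whose lactate output is unbounded above), and the
#' problem is infeasible when `2 G < L` (each glucose yields at most two
#' lactates). Used as the independent oracle for [fba()] on the toy
#' network; only valid when the amino-acid and fatty-acid routes are
#' closed.
#'
#' @param glc glucose uptake bound.
#' @param o2 oxygen uptake bound.
#' @param lactate_floor minimum lactate export.
#' @param spec the [toy_network_spec()] the network was built from.
#' @return maximal ATP yield, or `NA_real_` when infeasible.
#' @export
toy_closed_form_atp <- function(glc, o2, lactate_floor = 0,
                                spec = toy_network_spec()) {
  stopifnot(glc >= 0, o2 >= 0, lactate_floor >= 0)
  if (2 * glc < lactate_floor - 1e-12) return(NA_real_)
  g_ox <- max(0, min(glc - lactate_floor / 2, o2 / spec$o2_per_glucose))
  g_gly <- glc - g_ox
  spec$atp_per_glucose_oxidation * g_ox +
    spec$atp_per_glucose_glycolysis * g_gly
}

#' Generate expression profiles with planted category structure
#'
#' Per cell type, plants exact fractions of not-present (values below the
#' detection threshold) and missing (`NA`) genes; the remaining present
#' genes draw log-normal values whose ground-truth LOW/MEDIUM/HIGH labels
#' are derived from their rank against the interpolation-quantile
#' boundaries, so [discretize()] recovers them for all non-boundary genes.
#'
#' @param n_genes number of genes (>= 8).
#' @param cell_types character vector of profile labels.
#' @param fractions named fractions for `not_present` and `unknown`
#'   (missing) genes; the rest are present.
#' @param seed integer seed; fixed seed gives identical output.
#' @param threshold detection threshold (matches [discretize()]).
#' @return list with `profiles` (named list of `expression_profile`) and
#'   `truth` (named list of ground-truth category factors).
#' @export
make_expression <- function(n_genes = 1000,
                            cell_types = c("RPE", "rod", "cone"),
                            fractions = c(not_present = 0.05, unknown = 0.05),
                            seed = 1, threshold = 1e-5) {
  stopifnot(n_genes >= 8)
  genes <- sprintf("g%05d", seq_len(n_genes))
  n_np <- round(fractions[["not_present"]] * n_genes)
  n_na <- round(fractions[["unknown"]] * n_genes)
  n_present <- n_genes - n_np - n_na
  stopifnot(n_present >= 4)
  with_seed(seed, {
    out_prof <- list()
    out_truth <- list()
    for (ct in cell_types) {
      idx <- sample.int(n_genes)
      i_np <- idx[seq_len(n_np)]
      i_na <- idx[n_np + seq_len(n_na)]
      i_pr <- idx[-seq_len(n_np + n_na)]
      v <- stats::setNames(rep(NA_real_, n_genes), genes)
      v[i_np] <- stats::runif(n_np, 0, threshold * 0.99)
      pres <- stats::rlnorm(n_present, meanlog = 1, sdlog = 1) + threshold
      v[i_pr] <- pres
      truth <- rep("UNKNOWN", n_genes)
      truth[i_np] <- "NOT_PRESENT"
      r <- rank(pres, ties.method = "first")
      # positions at or below the type-7 quantile knots
      k1 <- floor(0.25 * (n_present - 1)) + 1
      k3 <- floor(0.75 * (n_present - 1)) + 1
      lab <- ifelse(r <= k1, "LOW", ifelse(r <= k3, "MEDIUM", "HIGH"))
      truth[i_pr] <- lab
      out_prof[[ct]] <- expression_profile(ct, v)
      out_truth[[ct]] <- factor(stats::setNames(truth, genes),
                                levels = .conf_levels)
    }
    list(profiles = out_prof, truth = out_truth)
  })
}

#' Specification for synthetic aging tables
#'
#' @param true_slope,true_intercept coefficients of the flow-deficit to
#'   CC-density calibration line (defaults: the regression coefficients
#'   `y = 72.6 - 1.29 x`).
#' @param noise_sd Gaussian noise (density percentage points) on the
#'   calibration pairs; rod densities get a relative log-normal noise of
#'   `noise_sd / 100`.
#' @param age_groups labels shared by the OCTA and rod tables.
#' @param eccentricities sampling grid in mm.
#' @param rod_peak_density,rod_peak_ecc parameters of the rod density hump
#'   curve `d(x) = dmax (x/x0)^2 exp(2 (1 - x/x0))`.
#' @param age_factors per-group multipliers on rod density; the default
#'   plants a non-monotone oldest group (0.85 after 0.78).
#' @param flow_deficit_base per-group central flow-deficit percentages,
#'   increasing with age.
#' @param seed integer seed.
#' @return a `synthetic_aging_spec`.
#' @export
synthetic_aging_spec <- function(true_slope = -1.29, true_intercept = 72.6,
                                 noise_sd = 0.5,
                                 age_groups = c("25", "45", "65", "80"),
                                 eccentricities = seq(0.5, 5, by = 0.5),
                                 rod_peak_density = 150000,
                                 rod_peak_ecc = 4,
                                 age_factors = c(1, 0.93, 0.78, 0.85),
                                 flow_deficit_base = c(5, 10, 16, 22),
                                 seed = 1) {
  stopifnot(length(age_factors) == length(age_groups),
            length(flow_deficit_base) == length(age_groups),
            all(diff(eccentricities) > 0))
  structure(list(true_slope = true_slope, true_intercept = true_intercept,
                 noise_sd = noise_sd, age_groups = age_groups,
                 eccentricities = eccentricities,
                 rod_peak_density = rod_peak_density,
                 rod_peak_ecc = rod_peak_ecc, age_factors = age_factors,
                 flow_deficit_base = flow_deficit_base, seed = seed),
            class = "synthetic_aging_spec")
}

# smooth rod density hump (Curcio-style profile shape)
rod_density_curve <- function(x, dmax, x0) {
  dmax * (x / x0)^2 * exp(2 * (1 - x / x0))
}

#' Generate synthetic aging tables
#'
#' Emulates the three inputs of the aging analysis: an OCTA table of flow
#' deficits by age group and eccentricity (increasing with age), histology
#' calibration pairs generated through the true calibration line plus
#' noise, rod density tables from a smooth hump curve scaled by age
#' factors (with a planted non-monotone oldest group), and a cone area
#' fraction profile declining with eccentricity.
#'
#' @param spec a [synthetic_aging_spec()].
#' @return list of data.frames: `octa` (age_group, eccentricity_mm,
#'   flow_deficit_pct), `calibration` (flow_deficit_pct, cc_density_pct),
#'   `rods` (age_group, eccentricity_mm, rod_density_per_mm2), `cones`
#'   (eccentricity_mm, cone_area_fraction).
#' @export
make_aging_dataset <- function(spec = synthetic_aging_spec()) {
  stopifnot(inherits(spec, "synthetic_aging_spec"))
  with_seed(spec$seed, {
    ng <- length(spec$age_groups)
    ecc <- spec$eccentricities
    octa <- do.call(rbind, lapply(seq_len(ng), function(g) {
      data.frame(age_group = spec$age_groups[g], eccentricity_mm = ecc,
                 flow_deficit_pct = spec$flow_deficit_base[g] + 3 * exp(-ecc),
                 stringsAsFactors = FALSE)
    }))

    fd <- seq(2, 30, length.out = 8)
    calibration <- data.frame(
      flow_deficit_pct = fd,
      cc_density_pct = spec$true_intercept + spec$true_slope * fd +
        stats::rnorm(length(fd), sd = spec$noise_sd))

    rods <- do.call(rbind, lapply(seq_len(ng), function(g) {
      d <- spec$age_factors[g] *
        rod_density_curve(ecc, spec$rod_peak_density, spec$rod_peak_ecc)
      d <- d * stats::rlnorm(length(ecc), sdlog = spec$noise_sd / 100)
      data.frame(age_group = spec$age_groups[g], eccentricity_mm = ecc,
                 rod_density_per_mm2 = d, stringsAsFactors = FALSE)
    }))

    cones <- data.frame(eccentricity_mm = ecc,
                        cone_area_fraction = 0.25 * exp(-1.2 * ecc) + 0.02)

    list(octa = octa, calibration = calibration, rods = rods, cones = cones)
  })
}

#' Planted gene confidences for the toy network
#'
#' Deterministic ground-truth confidence categories for the toy network's
#' genes, emulating what discretized expression data would assign: the RPE
#' expresses every route; photoreceptors lack the fatty-acid route
#' (NOT_PRESENT) and carry the amino-acid-to-lactate conversion at medium
#' confidence, with one unknown transporter and one low-confidence
#' isoenzyme for variety.
#'
#' @param cell_type `"RPE"`, `"rod"` or `"cone"`.
#' @return a `confidence_assignment` with gene-level categories (pass it
#'   through [score_reactions()] for reaction categories).
#' @export
toy_confidences <- function(cell_type = c("RPE", "rod", "cone")) {
  cell_type <- match.arg(cell_type)
  genes <- c("gTglc", "gTo2", "gTlac", "gGLYC1", "gGLYC2", "gOX1", "gOX2",
             "gTaa", "gAAOX", "gAALAC", "gTfa", "gFAOX")
  lv <- stats::setNames(rep("HIGH", length(genes)), genes)
  if (cell_type != "RPE") {
    lv[c("gTfa", "gFAOX")] <- "NOT_PRESENT"
    lv["gAALAC"] <- "MEDIUM"
    lv["gTo2"] <- "UNKNOWN"
    lv["gOX2"] <- "LOW"
  }
  structure(list(gene_conf = factor(lv, levels = .conf_levels),
                 rxn_conf = NULL, cell_type = cell_type),
            class = "confidence_assignment")
}

#' Build the toy control and retina-specific coupled models
#'
#' The control model couples two copies of the full toy template. The
#' retina-specific model couples cell-specific submodels extracted from
#' the planted confidences ([toy_confidences()]), with the ATP hydrolysis
#' demand and the template's exchange reactions restored after pruning —
#' the same construction the genome-scale pipeline uses.
#'
#' @param pr_cell photoreceptor cell type for the retina-specific model.
#' @param spec the [toy_network_spec()] for the template (amino-acid and
#'   fatty-acid routes enabled by default so constraint sweeps can open
#'   them).
#' @return named list of coupled `metabolic_model`s: `control`,
#'   `retina_specific`.
#' @export
toy_cell_models <- function(pr_cell = c("rod", "cone"),
                            spec = toy_network_spec(amino_acids = TRUE,
                                                    fatty_acids = TRUE)) {
  pr_cell <- match.arg(pr_cell)
  template <- make_toy_network(spec)
  mandatory <- c("ATPM", exchange_reactions(template)$reaction)
  build_cell <- function(ct) {
    conf <- score_reactions(template, toy_confidences(ct))
    sub <- extract_cell_model(template, conf, "BIOMASS")
    restore_mandatory(sub, template, mandatory)
  }
  list(control = couple(template, template),
       retina_specific = couple(build_cell("RPE"), build_cell(pr_cell)))
}

#' Write the synthetic fixture set to a directory
#'
#' Regenerates every fixture the pipeline needs: the toy network (single
#' cell, with amino-acid and fatty-acid routes) as SBML, expression
#' profiles as TSV, and the aging tables as TSV.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed for the stochastic generators.
#' @return `dir`, invisibly.
#' @export
simulate_fixtures <- function(dir, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- make_toy_network(toy_network_spec(amino_acids = TRUE,
                                         fatty_acids = TRUE))
  write_sbml(m, file.path(dir, "toy_network.xml"))
  expr <- make_expression(seed = seed)
  for (ct in names(expr$profiles)) {
    v <- expr$profiles[[ct]]$values
    utils::write.table(
      data.frame(gene_id = names(v), value = v),
      file.path(dir, paste0("expression_", ct, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  aging <- make_aging_dataset(synthetic_aging_spec(seed = seed))
  for (nm in names(aging)) {
    utils::write.table(aging[[nm]], file.path(dir, paste0("aging_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
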