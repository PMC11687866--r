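# Shared fixtures and independent oracles.

# Toy network with routes closed/open as needed; cached template specs.
toy_full_spec <- function() {
  toy_network_spec(amino_acids = TRUE, fatty_acids = TRUE)
}

# Independent oracle for the toy network's maximal ATP yield, including the
# amino-acid and fatty-acid routes: exhaustive vertex enumeration of the
# aggregated 5-variable LP
#   max  Ygly*ggly + Yox*gox + Yaa*aox + Yfa*fox
#   s.t. ggly + gox <= G;  alac + aox <= A;  fox <= FA;
#        o2g*gox + o2a*aox + o2f*fox <= O;  2*ggly + alac >= L;  vars >= 0.
# Every optimum of a bounded feasible LP sits on a vertex, so enumerating
# all 5-subsets of active constraints and keeping the best feasible basic
# solution is exact. Independent of the simplex implementation under test.
toy_vertex_oracle <- function(G, O, L = 0, A = 0, FA = 0,
                              spec = toy_full_spec()) {
  # variables: ggly, gox, aox, alac, fox
  Amat <- rbind(
    c(1, 1, 0, 0, 0),                                     # glucose
    c(0, 0, 1, 1, 0),                                     # amino acid
    c(0, 0, 0, 0, 1),                                     # fatty acid
    c(0, spec$o2_per_glucose, spec$o2_per_aa, 0, spec$o2_per_fa),  # oxygen
    c(-2, 0, 0, -1, 0),                                   # -lactate floor
    -diag(5))
  bvec <- c(G, A, FA, O, -L, rep(0, 5))
  obj <- c(spec$atp_per_glucose_glycolysis,
           spec$atp_per_glucose_oxidation,
           spec$atp_per_aa, 0, spec$atp_per_fa)
  best <- NA_real_
  idx <- utils::combn(nrow(Amat), 5)
  for (k in seq_len(ncol(idx))) {
    M <- Amat[idx[, k], , drop = FALSE]
    if (abs(det(M)) < 1e-10) next
    x <- solve(M, bvec[idx[, k]])
    if (all(Amat %*% x <= bvec + 1e-9)) {
      val <- sum(obj * x)
      if (is.na(best) || val > best) best <- val
    }
  }
  best  # NA when no feasible vertex exists (empty polytope)
}

# Canonical equality check for models (order-insensitive).
expect_models_equal <- function(a, b) {
  a <- retbudget:::canonicalize_model(a)
  b <- retbudget:::canonicalize_model(b)
  expect_identical(a$mets$id, b$mets$id)
  expect_identical(a$mets$compartment, b$mets$compartment)
  expect_identical(a$rxns$id, b$rxns$id)
  expect_equal(a$rxns$lower_bound, b$rxns$lower_bound, tolerance = 1e-12)
  expect_equal(a$rxns$upper_bound, b$rxns$upper_bound, tolerance = 1e-12)
  expect_identical(a$rxns$gpr, b$rxns$gpr)
  expect_identical(a$objective, b$objective)
  expect_true(max(abs(a$S - b$S)) == 0)
}

# confidence_assignment from a plain named character vector
conf_from <- function(categories) {
  structure(list(gene_conf = factor(categories,
                                    levels = retbudget:::.conf_levels),
                 rxn_conf = NULL),
            class = "confidence_assignment")
}

# apply plain uptake/floor bounds to a single-cell toy model
toy_with_bounds <- function(m, glc, o2, lac_floor = 0, aa = NULL, fa = NULL) {
  m <- set_bounds(m, "EX_glc", lower = -glc)
  m <- set_bounds(m, "EX_o2", lower = -o2)
  m <- set_bounds(m, "EX_lac", lower = lac_floor)
  if (!is.null(aa) && "EX_aa" %in% m$rxns$id) {
    m <- set_bounds(m, "EX_aa", lower = -aa)
  }
  if (!is.null(fa) && "EX_fa" %in% m$rxns$id) {
    m <- set_bounds(m, "EX_fa", lower = -fa)
  }
  m
}
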