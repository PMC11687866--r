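# Context-specific submodel extraction in the cost-optimisation
# reaction-dependency style: high-confidence reactions anchor the model and
# lower-confidence reactions are retained only where a cost-minimising flux
# distribution needs them to support a high-confidence reaction or biomass
# production. The dependency assessment is a deterministic reformulation:
# each reaction class carries a cost per unit absolute flux and, for every
# target, one weighted-minimum-flux LP is solved; every reaction used above
# a small tolerance in any such solution is retained.

.corda_costs <- c(HIGH = 0, MEDIUM = 1, UNKNOWN = 1, LOW = 10,
                  NOT_PRESENT = 1000)

#' Extract a cell-specific submodel from reaction confidences
#'
#' Retains (i) every HIGH-confidence reaction that can carry flux, (ii)
#' MEDIUM/LOW/UNKNOWN reactions only where cost-minimising support of a
#' HIGH reaction or of biomass requires them, and (iii) NOT_PRESENT
#' reactions only when indispensable for biomass or a HIGH target (these are
#' flagged in the `forced_low_confidence` attribute). Biomass can carry
#' positive flux in the result whenever it can in the template.
#'
#' @param template a `metabolic_model` (the generic network).
#' @param conf a `confidence_assignment` with reaction confidences from
#'   [score_reactions()].
#' @param biomass_id reaction id of the biomass (objective) equation.
#' @param epsilon activation flux each target must carry (default `1e-4`).
#' @param flux_tol absolute flux above which a reaction counts as used.
#' @param costs named cost-per-unit-flux vector over the five categories.
#' @return a `metabolic_model`; attribute `forced_low_confidence` lists
#'   NOT_PRESENT reactions that had to be kept.
#' @export
extract_cell_model <- function(template, conf, biomass_id,
                               epsilon = 1e-4, flux_tol = 1e-8,
                               costs = .corda_costs) {
  stopifnot(inherits(conf, "confidence_assignment"), !is.null(conf$rxn_conf))
  if (!biomass_id %in% template$rxns$id) {
    stop("biomass reaction not in template: ", biomass_id)
  }
  rconf <- as.character(conf$rxn_conf)[match(template$rxns$id,
                                             names(conf$rxn_conf))]
  rconf[is.na(rconf)] <- "UNKNOWN"
  w <- unname(costs[rconf])

  check <- lp_model(template,
                    as.numeric(template$rxns$id == biomass_id),
                    maximize = TRUE)
  if (check$status != "optimal" || check$value < epsilon) {
    stop("template cannot produce biomass")
  }

  high <- template$rxns$id[rconf == "HIGH"]
  targets <- unique(c(biomass_id, high))
  keep <- character(0)
  n <- nrow(template$rxns)
  for (tid in targets) {
    j <- match(tid, template$rxns$id)
    row <- matrix(as.numeric(template$rxns$id == tid), nrow = 1)
    sol <- NULL
    if (template$rxns$upper_bound[j] >= epsilon) {
      sol <- lp_min_weighted_abs(template, w, A = row, dir = ">=",
                                 rhs = epsilon)
      if (sol$status != "optimal") sol <- NULL
    }
    if (is.null(sol) && template$rxns$lower_bound[j] <= -epsilon) {
      sol <- lp_min_weighted_abs(template, w, A = row, dir = "<=",
                                 rhs = -epsilon)
      if (sol$status != "optimal") sol <- NULL
    }
    if (is.null(sol)) next  # target cannot carry flux; drop it
    keep <- union(keep, template$rxns$id[abs(sol$v) > flux_tol])
  }
  if (!length(keep)) stop("no reaction can carry flux in the template")
  sub <- subset_model(template, keep)
  sub <- set_objective(sub, biomass_id, "max")
  forced <- intersect(keep, template$rxns$id[rconf == "NOT_PRESENT"])
  attr(sub, "forced_low_confidence") <- forced
  attr(sub, "confidence") <- stats::setNames(rconf, template$rxns$id)[sub$rxns$id]
  sub
}

#' Restore mandatory reactions after extraction
#'
#' Adds back, from the template, reactions that pruning removed but that the
#' downstream pipeline requires — typically the ATP hydrolysis reaction and
#' the template's full exchange-reaction set. Idempotent: reactions already
#' present are untouched.
#'
#' @param cell_model the extracted `metabolic_model`.
#' @param template the template `metabolic_model`.
#' @param mandatory_ids reaction ids that must be present; ids absent from
#'   the template are an error.
#' @return the extended `metabolic_model`.
#' @export
restore_mandatory <- function(cell_model, template, mandatory_ids) {
  out <- add_reactions_from(cell_model, template, mandatory_ids)
  attr(out, "forced_low_confidence") <- attr(cell_model, "forced_low_confidence")
  out
}
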