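#' Construct a stoichiometric metabolic model
#'
#' A `metabolic_model` is a compartmentalised stoichiometric network: a set of
#' metabolites, a set of reactions with flux bounds and gene-protein-reaction
#' (GPR) rules, and at most one objective reaction. Fluxes are expressed in
#' pmol.s-1.mm-2 of retinal surface throughout the package.
#'
#' Exchange reactions follow the SBML/FBC community sign convention: they are
#' written `metabolite -> (nothing)`, so positive flux is export from the
#' system and uptake is negative flux (an uptake limit U becomes
#' `lower_bound = -U`).
#'
#' @param id model identifier (token).
#' @param metabolites data.frame with columns `id`, `name`, `compartment`.
#' @param reactions list of reaction descriptions; each element is a list with
#'   fields `id`, `stoich` (named numeric, metabolite id -> signed
#'   coefficient), `lower_bound`, `upper_bound`, and optional `gpr` (string
#'   boolean expression over gene ids, `and`/`or`/parentheses) and
#'   `subsystem`.
#' @param objective `NULL`, or list with `reaction` (a reaction id) and
#'   `direction` (`"max"` or `"min"`).
#'
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, metabolites, reactions, objective = NULL) {
  stopifnot(is.character(id), length(id) == 1L)
  mets <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  if (!all(c("id", "compartment") %in% names(mets))) {
    stop("metabolites need columns 'id' and 'compartment'")
  }
  if (is.null(mets$name)) mets$name <- mets$id
  mets <- mets[, c("id", "name", "compartment")]
  if (anyDuplicated(mets$id)) {
    stop("duplicate metabolite ids: ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  }
  if (any(!nzchar(mets$compartment))) stop("empty compartment")

  if (length(reactions) == 0L) stop("model needs at least one reaction")
  rid <- vapply(reactions, function(r) r$id, character(1))
  if (anyDuplicated(rid)) {
    stop("duplicate reaction ids: ",
         paste(unique(rid[duplicated(rid)]), collapse = ", "))
  }
  lb <- vapply(reactions, function(r) as.numeric(r$lower_bound), numeric(1))
  ub <- vapply(reactions, function(r) as.numeric(r$upper_bound), numeric(1))
  if (any(lb > ub)) {
    stop("lower_bound > upper_bound for: ", paste(rid[lb > ub], collapse = ", "))
  }
  gpr <- vapply(reactions, function(r) {
    g <- r$gpr
    if (is.null(g) || is.na(g) || !nzchar(g)) "" else gpr_format(gpr_parse(g))
  }, character(1))
  subsystem <- vapply(reactions, function(r) {
    s <- r$subsystem
    if (is.null(s)) "" else as.character(s)
  }, character(1))

  trip <- lapply(seq_along(reactions), function(j) {
    st <- reactions[[j]]$stoich
    if (length(st) == 0L) stop("empty stoichiometry in reaction ", rid[j])
    bad <- setdiff(names(st), mets$id)
    if (length(bad)) {
      stop("reaction ", rid[j], " references unknown metabolites: ",
           paste(bad, collapse = ", "))
    }
    cbind(match(names(st), mets$id), j, as.numeric(st))
  })
  trip <- do.call(rbind, trip)
  S <- Matrix::sparseMatrix(i = trip[, 1], j = trip[, 2], x = trip[, 3],
                            dims = c(nrow(mets), length(reactions)),
                            dimnames = list(mets$id, rid))

  m <- structure(list(
    id = id,
    mets = mets,
    rxns = data.frame(id = rid, lower_bound = lb, upper_bound = ub,
                      gpr = gpr, subsystem = subsystem,
                      stringsAsFactors = FALSE),
    S = S,
    objective = NULL
  ), class = "metabolic_model")
  if (!is.null(objective)) m <- set_objective(m, objective$reaction,
                                              objective$direction)
  m
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n", sep = "")
  cat("  metabolites: ", nrow(x$mets), " in ",
      length(unique(x$mets$compartment)), " compartments\n", sep = "")
  cat("  reactions:   ", nrow(x$rxns), "\n", sep = "")
  if (is.null(x$objective)) {
    cat("  objective:   <none>\n")
  } else {
    cat("  objective:   ", x$objective$direction, " ",
        x$objective$reaction, "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.metabolic_model <- function(object, ...) {
  comp <- table(object$mets$compartment)
  ex <- exchange_reactions(object)
  out <- list(id = object$id, n_metabolites = nrow(object$mets),
              n_reactions = nrow(object$rxns), compartments = comp,
              n_exchanges = nrow(ex), objective = object$objective)
  class(out) <- "summary.metabolic_model"
  out
}

#' @export
print.summary.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, ": ", x$n_metabolites, " metabolites, ",
      x$n_reactions, " reactions (", x$n_exchanges, " exchanges)\n", sep = "")
  cat("  compartments:", paste(names(x$compartments), collapse = ", "), "\n")
  invisible(x)
}

#' Set or replace the model objective
#'
#' @param model a `metabolic_model`.
#' @param reaction a reaction id present in the model.
#' @param direction `"max"` or `"min"`.
#' @return the modified model.
#' @export
set_objective <- function(model, reaction, direction = c("max", "min")) {
  direction <- match.arg(direction)
  if (!reaction %in% model$rxns$id) {
    stop("objective reaction not in model: ", reaction)
  }
  model$objective <- list(reaction = reaction, direction = direction)
  model
}

#' Set flux bounds on a reaction
#'
#' @param model a `metabolic_model`.
#' @param reaction a reaction id.
#' @param lower,upper new bounds; `NA` keeps the current value.
#' @return the modified model.
#' @export
set_bounds <- function(model, reaction, lower = NA, upper = NA) {
  i <- match(reaction, model$rxns$id)
  if (is.na(i)) stop("no such reaction: ", reaction)
  if (!is.na(lower)) model$rxns$lower_bound[i] <- lower
  if (!is.na(upper)) model$rxns$upper_bound[i] <- upper
  if (model$rxns$lower_bound[i] > model$rxns$upper_bound[i]) {
    stop("lower_bound > upper_bound for ", reaction)
  }
  model
}

#' Identify exchange (boundary) reactions
#'
#' An exchange reaction involves exactly one metabolite; by the sign
#' convention used here positive flux is export and negative flux uptake.
#'
#' @param model a `metabolic_model`.
#' @param compartment optional compartment filter on the exchanged metabolite.
#' @return data.frame with columns `reaction`, `metabolite`, `compartment`,
#'   `coefficient`, `lower_bound`, `upper_bound`.
#' @export
exchange_reactions <- function(model, compartment = NULL) {
  nz <- Matrix::colSums(model$S != 0)
  j <- which(nz == 1L)
  if (!length(j)) {
    return(data.frame(reaction = character(0), metabolite = character(0),
                      compartment = character(0), coefficient = numeric(0),
                      lower_bound = numeric(0), upper_bound = numeric(0)))
  }
  met <- vapply(j, function(k) model$mets$id[which(model$S[, k] != 0)],
                character(1))
  coef <- vapply(seq_along(j), function(k) model$S[met[k], j[k]], numeric(1))
  out <- data.frame(reaction = model$rxns$id[j], metabolite = met,
                    compartment = model$mets$compartment[match(met, model$mets$id)],
                    coefficient = coef,
                    lower_bound = model$rxns$lower_bound[j],
                    upper_bound = model$rxns$upper_bound[j],
                    stringsAsFactors = FALSE)
  if (!is.null(compartment)) out <- out[out$compartment %in% compartment, ]
  rownames(out) <- NULL
  out
}

#' Extract a submodel restricted to a reaction set
#'
#' Keeps the named reactions with their bounds and GPRs, and drops
#' metabolites no longer referenced by any kept reaction.
#'
#' @param model a `metabolic_model`.
#' @param reaction_ids character vector of reaction ids to keep.
#' @return a `metabolic_model`.
#' @export
subset_model <- function(model, reaction_ids) {
  keep <- model$rxns$id %in% reaction_ids
  if (!any(keep)) stop("no reactions kept")
  S <- model$S[, keep, drop = FALSE]
  used <- Matrix::rowSums(S != 0) > 0
  rx <- model$rxns[keep, , drop = FALSE]
  reactions <- lapply(seq_len(nrow(rx)), function(j) {
    col <- S[, j]
    nzi <- which(col != 0)
    list(id = rx$id[j], stoich = stats::setNames(col[nzi], rownames(S)[nzi]),
         lower_bound = rx$lower_bound[j], upper_bound = rx$upper_bound[j],
         gpr = rx$gpr[j], subsystem = rx$subsystem[j])
  })
  obj <- model$objective
  if (!is.null(obj) && !obj$reaction %in% rx$id) obj <- NULL
  metabolic_model(model$id, model$mets[used, , drop = FALSE], reactions,
                  objective = obj)
}

#' Merge reactions from a template into a model
#'
#' Adds the named reactions (with template stoichiometry, bounds and GPRs)
#' to `model`, together with any metabolites they reference. Reactions
#' already present are left untouched, so the operation is idempotent.
#'
#' @param model a `metabolic_model` to extend.
#' @param template the `metabolic_model` supplying reaction definitions.
#' @param reaction_ids character vector of reaction ids to guarantee present.
#' @return the extended model.
#' @export
add_reactions_from <- function(model, template, reaction_ids) {
  missing_tpl <- setdiff(reaction_ids, template$rxns$id)
  if (length(missing_tpl)) {
    stop("not in template: ", paste(missing_tpl, collapse = ", "))
  }
  need <- setdiff(reaction_ids, model$rxns$id)
  if (!length(need)) return(model)
  reactions <- reaction_list(model)
  tpl <- reaction_list(template)
  names(tpl) <- template$rxns$id
  reactions <- c(reactions, tpl[need])
  met_ids <- unique(c(model$mets$id,
                      unlist(lapply(tpl[need], function(r) names(r$stoich)))))
  mets <- rbind(model$mets,
                template$mets[template$mets$id %in%
                                setdiff(met_ids, model$mets$id), , drop = FALSE])
  metabolic_model(model$id, mets, reactions, objective = model$objective)
}

# internal: model reactions as a constructor-style list
reaction_list <- function(model) {
  lapply(seq_len(nrow(model$rxns)), function(j) {
    col <- model$S[, j]
    nzi <- which(col != 0)
    list(id = model$rxns$id[j],
         stoich = stats::setNames(col[nzi], model$mets$id[nzi]),
         lower_bound = model$rxns$lower_bound[j],
         upper_bound = model$rxns$upper_bound[j],
         gpr = model$rxns$gpr[j], subsystem = model$rxns$subsystem[j])
  })
}

# internal: canonical reordering (sorted ids) for deterministic output
canonicalize_model <- function(model) {
  mo <- order(model$mets$id)
  ro <- order(model$rxns$id)
  model$mets <- model$mets[mo, , drop = FALSE]
  rownames(model$mets) <- NULL
  model$rxns <- model$rxns[ro, , drop = FALSE]
  rownames(model$rxns) <- NULL
  model$S <- model$S[mo, ro, drop = FALSE]
  model
}

#' Export a flux table as TSV
#'
#' Writes reaction_id, flux, lower_bound, upper_bound for every reaction.
#'
#' @param solution a `flux_solution` from [fba()] or [pfba()].
#' @param model the model the solution belongs to.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_flux_tsv <- function(solution, model, path) {
  stopifnot(inherits(solution, "flux_solution"))
  tab <- data.frame(reaction_id = model$rxns$id,
                    flux = unname(solution$fluxes[model$rxns$id]),
                    lower_bound = model$rxns$lower_bound,
                    upper_bound = model$rxns$upper_bound)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
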