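#' Suffix and compartment conventions for RPE-PR coupling
#'
#' The coupled model carries every metabolite and reaction id with its cell
#' suffix, a shared extracellular interface compartment between the two
#' cells, and distinct suffixes for the interface duplicates contributed by
#' each side.
#'
#' @param rpe_suffix,pr_suffix id suffixes for the two cell models.
#' @param interface_compartment compartment id of the shared RPE-PR
#'   extracellular interface.
#' @param rpe_dup_suffix,pr_dup_suffix reaction-id suffixes for interface
#'   duplicates of RPE-side and PR-side reactions.
#' @param interface_only_suffix reaction-id suffix for duplicates involving
#'   only the interface compartment.
#' @param extracellular compartment id of the extracellular space in the
#'   input models.
#' @return a `coupling_spec`.
#' @export
coupling_spec <- function(rpe_suffix = "_RPE", pr_suffix = "_PR",
                          interface_compartment = "e_RPE_PR",
                          rpe_dup_suffix = "_RPE-PR",
                          pr_dup_suffix = "_PR_RPE",
                          interface_only_suffix = "_eRPE_PR",
                          extracellular = "e") {
  sufs <- c(rpe_suffix, pr_suffix, rpe_dup_suffix, pr_dup_suffix,
            interface_only_suffix)
  if (any(!nzchar(sufs)) || anyDuplicated(sufs)) {
    stop("coupling suffixes must be non-empty and pairwise distinct")
  }
  structure(list(rpe_suffix = rpe_suffix, pr_suffix = pr_suffix,
                 interface_compartment = interface_compartment,
                 rpe_dup_suffix = rpe_dup_suffix,
                 pr_dup_suffix = pr_dup_suffix,
                 interface_only_suffix = interface_only_suffix,
                 extracellular = extracellular),
            class = "coupling_spec")
}

# interface metabolite id for a pre-rename extracellular metabolite
interface_met_id <- function(base_id) paste0(base_id, "_RPE_PR")

#' Couple an RPE model and a PR model through a shared interface
#'
#' Fuses the two models into one: every id carries its cell suffix; every
#' reaction that links the extracellular space to the cell interior (and
#' every purely extracellular reaction) is duplicated with its extracellular
#' species redirected to the shared interface compartment; after fusion,
#' reactions with identical stoichiometric signatures are merged keeping the
#' widest bounds. Exchange (boundary) reactions are not duplicated, so the
#' result keeps exactly two circulation interfaces — the RPE-side and
#' PR-side extracellular compartments.
#'
#' @param rpe,pr `metabolic_model`s for the two cells, each with an
#'   extracellular compartment and at least one reaction touching it.
#' @param spec a [coupling_spec()].
#' @return a `metabolic_model`; attribute `coupling_counts` records the
#'   bookkeeping (reactions from each side, duplicates created, duplicates
#'   merged away).
#' @export
couple <- function(rpe, pr, spec = coupling_spec()) {
  a <- couple_side(rpe, spec$rpe_suffix, spec$rpe_dup_suffix, spec)
  b <- couple_side(pr, spec$pr_suffix, spec$pr_dup_suffix, spec)

  mets <- rbind(a$mets, b$mets)
  mets <- mets[!duplicated(mets$id), , drop = FALSE]
  reactions <- c(a$reactions, b$reactions)

  # merge reactions with identical stoichiometric signatures, keeping the
  # lexicographically first id and the widest bounds
  sig <- vapply(reactions, function(r) {
    o <- order(names(r$stoich))
    paste(names(r$stoich)[o], format(r$stoich[o], digits = 12),
          sep = ":", collapse = ";")
  }, character(1))
  rid <- vapply(reactions, `[[`, character(1), "id")
  merged <- 0L
  keep <- logical(length(reactions))
  for (g in split(seq_along(reactions), sig)) {
    k <- g[order(rid[g])][1]
    keep[k] <- TRUE
    if (length(g) > 1L) {
      merged <- merged + length(g) - 1L
      reactions[[k]]$lower_bound <- min(vapply(reactions[g], `[[`, numeric(1), "lower_bound"))
      reactions[[k]]$upper_bound <- max(vapply(reactions[g], `[[`, numeric(1), "upper_bound"))
    }
  }
  reactions <- reactions[keep]
  rid <- rid[keep]
  if (anyDuplicated(rid)) {
    stop("id collision after coupling: ",
         paste(unique(rid[duplicated(rid)]), collapse = ", "))
  }

  out <- metabolic_model(paste0(rpe$id, "-", pr$id, "_coupled"),
                         mets, reactions, objective = NULL)
  out <- canonicalize_model(out)
  attr(out, "coupling_counts") <- c(
    rpe = nrow(rpe$rxns), pr = nrow(pr$rxns),
    duplicates = a$n_dup + b$n_dup, merged = merged,
    coupled = nrow(out$rxns))
  out
}

# rename one side and build its interface duplicates
couple_side <- function(model, suffix, dup_suffix, spec) {
  e <- spec$extracellular
  if (!e %in% model$mets$compartment) {
    stop("model '", model$id, "' has no extracellular compartment '", e, "'")
  }
  if (any(endsWith(model$mets$id, suffix)) ||
      any(endsWith(model$rxns$id, suffix))) {
    stop("suffix '", suffix, "' collides with existing ids in '",
         model$id, "'")
  }
  is_e <- stats::setNames(model$mets$compartment == e, model$mets$id)
  rl <- reaction_list(model)
  touches_e <- vapply(rl, function(r) any(is_e[names(r$stoich)]), logical(1))
  if (!any(touches_e)) {
    stop("model '", model$id, "' has no reactions involving the extracellular compartment")
  }
  n_met <- vapply(rl, function(r) length(r$stoich), integer(1))
  only_e <- vapply(rl, function(r) all(is_e[names(r$stoich)]), logical(1))
  is_exchange <- touches_e & n_met == 1L

  mets <- model$mets
  mets$id <- paste0(mets$id, suffix)
  mets$compartment <- paste0(mets$compartment, suffix)

  renamed <- lapply(rl, function(r) {
    r$stoich <- stats::setNames(r$stoich, paste0(names(r$stoich), suffix))
    r$id <- paste0(r$id, suffix)
    r
  })

  dup_idx <- which(touches_e & !is_exchange)
  dups <- lapply(dup_idx, function(j) {
    r <- rl[[j]]
    nm <- names(r$stoich)
    nm <- ifelse(is_e[nm], interface_met_id(nm), paste0(nm, suffix))
    r$stoich <- stats::setNames(r$stoich, nm)
    r$id <- paste0(r$id, if (only_e[j]) spec$interface_only_suffix else dup_suffix)
    r
  })

  iface_base <- model$mets[is_e[model$mets$id], , drop = FALSE]
  iface <- data.frame(id = interface_met_id(iface_base$id),
                      name = iface_base$name,
                      compartment = spec$interface_compartment,
                      stringsAsFactors = FALSE)
  used <- unique(unlist(lapply(dups, function(r) names(r$stoich))))
  iface <- iface[iface$id %in% used, , drop = FALSE]

  list(mets = rbind(mets, iface), reactions = c(renamed, dups),
       n_dup = length(dups))
}

#' Structural report on a coupled model
#'
#' Lists compartments, interface reaction counts, orphan metabolites
#' (referenced by no reaction) and dead-end metabolites in the interface
#' compartment (metabolites that cannot be both produced and consumed under
#' the current bounds). Report-only: never raises an error.
#'
#' @param model a coupled `metabolic_model`.
#' @param spec the [coupling_spec()] used to build it.
#' @return a `coupling_report`.
#' @export
validate_coupled <- function(model, spec = coupling_spec()) {
  comps <- sort(unique(model$mets$compartment))
  suffix_count <- function(suf) sum(endsWith(model$rxns$id, suf))
  iface_counts <- c(
    rpe_side = suffix_count(spec$rpe_dup_suffix),
    pr_side = suffix_count(spec$pr_dup_suffix),
    interface_only = suffix_count(spec$interface_only_suffix))

  deg <- Matrix::rowSums(model$S != 0)
  orphans <- model$mets$id[deg == 0]

  iface_mets <- model$mets$id[model$mets$compartment == spec$interface_compartment]
  dead <- character(0)
  for (m in iface_mets) {
    row <- model$S[m, ]
    j <- which(row != 0)
    can_prod <- any((row[j] > 0 & model$rxns$upper_bound[j] > 0) |
                      (row[j] < 0 & model$rxns$lower_bound[j] < 0))
    can_cons <- any((row[j] < 0 & model$rxns$upper_bound[j] > 0) |
                      (row[j] > 0 & model$rxns$lower_bound[j] < 0))
    if (!(can_prod && can_cons)) dead <- c(dead, m)
  }

  structure(list(compartments = comps,
                 interface_reaction_counts = iface_counts,
                 orphan_metabolites = orphans,
                 interface_dead_ends = dead,
                 counts = attr(model, "coupling_counts")),
            class = "coupling_report")
}

#' @export
print.coupling_report <- function(x, ...) {
  cat("<coupling_report>\n")
  cat("  compartments:", paste(x$compartments, collapse = ", "), "\n")
  cat("  interface reactions:",
      paste(names(x$interface_reaction_counts),
            x$interface_reaction_counts, sep = "=", collapse = " "), "\n")
  cat("  orphan metabolites:", length(x$orphan_metabolites), "\n")
  cat("  interface dead ends:", length(x$interface_dead_ends),
      if (length(x$interface_dead_ends))
        paste0("(", paste(x$interface_dead_ends, collapse = ", "), ")") else "",
      "\n")
  invisible(x)
}

#' Write a coupling report as JSON lines
#'
#' @param report a `coupling_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_coupling_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (field in names(unclass(report))) {
    writeLines(jsonlite::toJSON(
      list(field = field, value = report[[field]]), auto_unbox = TRUE), con)
  }
  invisible(path)
}
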