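#' Flux balance analysis
#'
#' Solves the linear program max (or min) `c'v` subject to steady-state mass
#' balance `S v = 0` and the model's flux bounds, where the objective vector
#' selects the model's objective reaction.
#'
#' @param model a `metabolic_model` with an objective set (see
#'   [set_objective()]).
#' @return a `flux_solution`: list with `status` (`"optimal"`,
#'   `"infeasible"` or `"unbounded"`), `objective_value`, and `fluxes`
#'   (named numeric over reactions). For non-optimal statuses
#'   `objective_value` is `NA`.
#' @export
fba <- function(model) {
  if (is.null(model$objective)) {
    stop("model has no objective; set one with set_objective()")
  }
  obj <- as.numeric(model$rxns$id == model$objective$reaction)
  res <- lp_model(model, obj, maximize = model$objective$direction == "max")
  as_flux_solution(res, model)
}

as_flux_solution <- function(res, model) {
  if (res$status == "optimal" && abs(res$value) >= 0.99 * .lp_big) {
    # optimum pinned at the numerical bound clamp: treat as unbounded
    return(structure(list(status = "unbounded", objective_value = NA_real_,
                          fluxes = NULL), class = "flux_solution"))
  }
  if (res$status != "optimal") {
    return(structure(list(status = "infeasible", objective_value = NA_real_,
                          fluxes = NULL), class = "flux_solution"))
  }
  fl <- stats::setNames(res$v, model$rxns$id)
  resid <- max(abs(as.numeric(model$S %*% fl)))
  if (resid > 1e-6) {
    stop("steady-state residual ", format(resid), " exceeds tolerance")
  }
  structure(list(status = "optimal", objective_value = res$value,
                 fluxes = fl), class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status: ", x$status, sep = "")
  if (x$status == "optimal") {
    cat(", objective = ", format(x$objective_value, digits = 6), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Flux variability analysis
#'
#' For each requested reaction, minimises and maximises its flux subject to
#' the steady-state constraints, the bounds, and the requirement that the
#' objective stays at or above `objective_fraction` times its optimum.
#'
#' @param model a `metabolic_model` with an objective.
#' @param reaction_ids reactions to analyse (default: all).
#' @param objective_fraction fraction of the FBA optimum to retain, in
#'   `[0, 1]`.
#' @return data.frame with columns `reaction`, `min_flux`, `max_flux`.
#' @export
fva <- function(model, reaction_ids = model$rxns$id,
                objective_fraction = 1.0) {
  stopifnot(objective_fraction >= 0, objective_fraction <= 1)
  base <- fba(model)
  if (base$status != "optimal") {
    stop("base FBA problem is ", base$status)
  }
  obj <- as.numeric(model$rxns$id == model$objective$reaction)
  maximize <- model$objective$direction == "max"
  Aobj <- matrix(obj, nrow = 1)
  rhs <- objective_fraction * base$objective_value
  dir <- if (maximize) ">=" else "<="
  out <- lapply(reaction_ids, function(rid) {
    j <- match(rid, model$rxns$id)
    if (is.na(j)) stop("no such reaction: ", rid)
    cvec <- as.numeric(model$rxns$id == rid)
    lo <- lp_model(model, cvec, maximize = FALSE, A = Aobj, dir = dir,
                   rhs = rhs)
    hi <- lp_model(model, cvec, maximize = TRUE, A = Aobj, dir = dir,
                   rhs = rhs)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("FVA subproblem for ", rid, " is infeasible")
    }
    c(min_flux = lo$value, max_flux = hi$value)
  })
  out <- do.call(rbind, out)
  data.frame(reaction = reaction_ids, min_flux = out[, 1],
             max_flux = out[, 2], row.names = NULL)
}

#' Parsimonious flux balance analysis
#'
#' Among flux vectors attaining the FBA optimum, returns one minimising the
#' total absolute flux `sum |v|`. FBA optima are typically degenerate;
#' pFBA makes reported flux vectors reproducible across solvers.
#'
#' @param model a `metabolic_model` with an objective.
#' @return a `flux_solution` whose `objective_value` equals the FBA optimum.
#' @export
pfba <- function(model) {
  base <- fba(model)
  if (base$status != "optimal") return(base)
  obj <- as.numeric(model$rxns$id == model$objective$reaction)
  res <- lp_min_weighted_abs(model, weights = rep(1, nrow(model$rxns)),
                             A = matrix(obj, nrow = 1), dir = "=",
                             rhs = base$objective_value)
  if (res$status != "optimal") {
    # pinned objective can sit on a numerically awkward facet; relax to a
    # one-sided constraint at the optimum
    dir <- if (model$objective$direction == "max") ">=" else "<="
    res <- lp_min_weighted_abs(model, weights = rep(1, nrow(model$rxns)),
                               A = matrix(obj, nrow = 1), dir = dir,
                               rhs = base$objective_value)
  }
  if (res$status != "optimal") stop("pFBA subproblem failed: ", res$status)
  sol <- as_flux_solution(list(status = "optimal",
                               value = sum(obj * res$v), v = res$v), model)
  sol$total_flux <- sum(abs(res$v))
  sol
}

#' Detect internal loops in a flux solution
#'
#' Sign-constrained null-space test: a flux vector contains an internal
#' (thermodynamically infeasible) cycle if some non-zero circulation through
#' internal reactions matches the solution's flux signs. Used as an optional
#' post-check; reported flux vectors come from [pfba()], which already
#' suppresses gratuitous cycles.
#'
#' @param model a `metabolic_model`.
#' @param solution a `flux_solution` with fluxes.
#' @param tol flux magnitude below which a reaction counts as inactive.
#' @return list with `has_loop` (logical) and `reactions` (ids implicated).
#' @export
loop_check <- function(model, solution, tol = 1e-7) {
  stopifnot(inherits(solution, "flux_solution"))
  if (is.null(solution$fluxes)) {
    return(list(has_loop = FALSE, reactions = character(0)))
  }
  ex <- exchange_reactions(model)$reaction
  internal <- setdiff(model$rxns$id, ex)
  active <- internal[abs(solution$fluxes[internal]) > tol]
  if (length(active) < 2L) {
    return(list(has_loop = FALSE, reactions = character(0)))
  }
  # is there a circulation w (S_internal w = 0, w != 0) whose signs agree
  # with the active fluxes? Solve an LP: maximise sum w_j sign_j subject to
  # S w = 0, 0 <= w_j sign_j <= 1, inactive internal reactions and all
  # exchanges fixed to zero.
  n <- nrow(model$rxns)
  sgn <- sign(solution$fluxes[model$rxns$id])
  lb <- numeric(n); ub <- numeric(n)
  act <- model$rxns$id %in% active
  ub[act & sgn > 0] <- 1
  lb[act & sgn < 0] <- -1
  obj <- as.numeric(act) * sgn
  res <- lp_solve_raw(obj, Aeq = as.matrix(model$S), beq = numeric(nrow(model$S)),
                      lb = lb, ub = ub, maximize = TRUE)
  if (res$status != "optimal" || res$value <= tol) {
    return(list(has_loop = FALSE, reactions = character(0)))
  }
  list(has_loop = TRUE,
       reactions = model$rxns$id[abs(res$v) > tol])
}
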