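# Maximal ATP yield under blood-exchange constraints, and the parameter
# sweeps around it. Infeasibility is a first-class result value (a yield of
# NA with status "INFEASIBLE"), never an exception, so sweeps can cross the
# feasibility boundary.

constrain_model <- function(coupled, cs, map, modify = identity) {
  m <- apply_constraints(coupled, cs, map = map)
  modify(m)
}

#' Maximal ATP yield of a constrained coupled model
#'
#' Applies the constraint set, sets the objective to maximise the PR ATP
#' hydrolysis flux, and solves by FBA. The reported flux vector comes from
#' pFBA, which picks the minimum-total-flux optimum so results are
#' reproducible across solvers; the yield itself is the FBA optimum.
#'
#' @param coupled a coupled `metabolic_model`.
#' @param cs a `constraint_set`.
#' @param objective id of the PR ATP hydrolysis reaction (default
#'   `"ATPM_PR"`, the toy analogue of the genome-scale ATP demand).
#' @param map metabolite name mapping, see [apply_constraints()].
#' @param model_tag label recorded in the result (`"control"` or
#'   `"retina_specific"`).
#' @param flux_vector logical; also compute the pFBA flux vector.
#' @return a `yield_result`: site, condition, amino_acids, model_tag,
#'   `status` (`"optimal"` or `"INFEASIBLE"`), `atp_yield` (NA when
#'   infeasible) and `solution` (a `flux_solution` or NULL).
#' @export
max_atp <- function(coupled, cs, objective = "ATPM_PR",
                    map = toy_metabolite_map(), model_tag = NA_character_,
                    flux_vector = FALSE) {
  m <- constrain_model(coupled, cs, map)
  m <- set_objective(m, objective, "max")
  sol <- fba(m)
  res <- structure(list(
    site = cs$site, condition = cs$condition,
    amino_acids = cs$amino_acids_enabled, model_tag = model_tag,
    status = if (sol$status == "optimal") "optimal" else "INFEASIBLE",
    atp_yield = if (sol$status == "optimal") sol$objective_value else NA_real_,
    solution = NULL), class = "yield_result")
  if (flux_vector && sol$status == "optimal") res$solution <- pfba(m)
  res
}

#' @export
print.yield_result <- function(x, ...) {
  cat("<yield_result> ", x$site, "/", x$condition,
      if (isTRUE(x$amino_acids)) " +AA" else " -AA",
      if (!is.na(x$model_tag)) paste0(" [", x$model_tag, "]") else "",
      ": ", sep = "")
  if (x$status == "optimal") {
    cat(format(x$atp_yield, digits = 4), "pmol/s/mm2\n")
  } else {
    cat("INFEASIBLE\n")
  }
  invisible(x)
}

# identify amino-acid rows of a constraint set (everything that is not a
# named core metabolite)
aa_rows <- function(cs) {
  !cs$bounds$metabolite %in% c("oxygen", "glucose", "lactate", "water")
}

#' Sweep the amino-acid uptake bounds
#'
#' Re-solves the maximal ATP yield with every amino-acid uptake bound
#' scaled by each multiplier. Yields are non-decreasing in the multiplier
#' (a larger bound only relaxes the problem).
#'
#' @param coupled a coupled `metabolic_model`.
#' @param cs a `constraint_set` with amino acids enabled.
#' @param multipliers scaling factors (default `c(0.25, 0.5, 1, 2)`).
#' @param ... passed to [max_atp()].
#' @return a `sweep_result` data.frame with columns `multiplier`, `status`,
#'   `atp_yield`; attribute `threshold` gives the smallest feasible
#'   multiplier when the sweep crosses the feasibility boundary.
#' @export
sweep_amino_acids <- function(coupled, cs, multipliers = c(0.25, 0.5, 1, 2),
                              ...) {
  if (!cs$amino_acids_enabled) {
    stop("constraint set has amino acids disabled")
  }
  multipliers <- sort(multipliers)
  sel <- aa_rows(cs)
  rows <- lapply(multipliers, function(m) {
    cs2 <- cs
    cs2$bounds$uptake_max[sel] <- cs$bounds$uptake_max[sel] * m
    r <- max_atp(coupled, cs2, ...)
    data.frame(multiplier = m, status = r$status, atp_yield = r$atp_yield)
  })
  out <- do.call(rbind, rows)
  feas <- out$status == "optimal"
  thr <- if (any(feas) && any(!feas)) min(out$multiplier[feas]) else NA_real_
  structure(out, threshold = thr, swept_parameter = "amino_acid_multiplier",
            class = c("sweep_result", "data.frame"))
}

#' Grid search for the feasibility threshold of an exchange bound
#'
#' Walks a fixed grid (default step 0.10 pmol.s-1.mm-2), either decreasing
#' an uptake bound from its configured value towards zero or increasing an
#' export floor from its configured value, and returns the last feasible
#' grid value before infeasibility. Grid search, not bisection, mirrors the
#' decrement procedure the threshold granularity comes from.
#'
#' @param coupled a coupled `metabolic_model`.
#' @param cs a `constraint_set`.
#' @param exchange constraint metabolite name (e.g. `"glucose"`,
#'   `"lactate"`).
#' @param direction `"decrease_uptake"` or `"increase_export"`.
#' @param step grid step (default 0.10).
#' @param max_steps cap on grid points explored upwards.
#' @param ... passed to [max_atp()].
#' @return a `feasibility_threshold`: list with `threshold` (last feasible
#'   grid value, NA when the boundary was never crossed), `open_boundary`
#'   flag, and the explored `values`/`feasible` grid.
#' @export
feasibility_threshold <- function(coupled, cs, exchange = "glucose",
                                  direction = c("decrease_uptake",
                                                "increase_export"),
                                  step = 0.10, max_steps = 200, ...) {
  direction <- match.arg(direction)
  sel <- cs$bounds$metabolite == exchange
  if (!any(sel)) stop("constraint set has no bounds for ", exchange)
  col <- if (direction == "decrease_uptake") "uptake_max" else "export_min"
  start <- max(cs$bounds[[col]][sel])
  if (direction == "decrease_uptake") {
    values <- seq(start, 0, by = -step)
    if (utils::tail(values, 1) > 1e-12) values <- c(values, 0)
  } else {
    values <- start + step * (0:max_steps)
  }
  feasible <- logical(0)
  threshold <- NA_real_
  open_boundary <- TRUE
  for (v in values) {
    cs2 <- cs
    scalefac <- if (start > 0) v / start else 0
    cs2$bounds[[col]][sel] <- cs$bounds[[col]][sel] * scalefac
    ok <- max_atp(coupled, cs2, ...)$status == "optimal"
    feasible <- c(feasible, ok)
    if (!ok) {
      open_boundary <- FALSE
      n <- length(feasible)
      threshold <- if (n > 1 && feasible[n - 1]) values[n - 1] else NA_real_
      break
    }
  }
  structure(list(exchange = exchange, direction = direction, step = step,
                 values = values[seq_along(feasible)], feasible = feasible,
                 threshold = threshold, open_boundary = open_boundary),
            class = "feasibility_threshold")
}

#' @export
print.feasibility_threshold <- function(x, ...) {
  cat("<feasibility_threshold> ", x$exchange, " (", x$direction, "): ",
      sep = "")
  if (x$open_boundary) {
    cat("open boundary (feasibility never changed on the grid)\n")
  } else if (is.na(x$threshold)) {
    cat("infeasible from the start\n")
  } else {
    cat("last feasible value ", format(x$threshold, digits = 4), "\n", sep = "")
  }
  invisible(x)
}

#' Effect of opening lipid pools on maximal ATP yield
#'
#' For each lipid-pool exchange reaction, opens its uptake to `bound` and
#' reports the change in maximal ATP yield against the baseline
#' constraint set. Gains are bounded by the spare oxygen capacity and
#' plateau once oxygen saturates.
#'
#' @param coupled a coupled `metabolic_model`.
#' @param cs a `constraint_set`.
#' @param pool_reactions exchange reaction ids of the lipid pools (toy
#'   default: the RPE-side fatty-acid exchange). Unknown ids are skipped
#'   with a warning.
#' @param bound uptake opened per pool (default 1.0 pmol.s-1.mm-2).
#' @param objective,map as in [max_atp()].
#' @return data.frame with columns `pool`, `baseline`, `opened`, `delta`.
#' @export
lipid_pool_test <- function(coupled, cs, pool_reactions = "EX_fa_RPE",
                            bound = 1.0, objective = "ATPM_PR",
                            map = toy_metabolite_map()) {
  base <- max_atp(coupled, cs, objective = objective, map = map)
  rows <- lapply(pool_reactions, function(rid) {
    if (!rid %in% coupled$rxns$id) {
      warning("unknown lipid pool reaction, skipped: ", rid)
      return(NULL)
    }
    m <- constrain_model(coupled, cs, map,
                         modify = function(m) set_bounds(m, rid, lower = -bound))
    m <- set_objective(m, objective, "max")
    sol <- fba(m)
    opened <- if (sol$status == "optimal") sol$objective_value else NA_real_
    data.frame(pool = rid, baseline = base$atp_yield, opened = opened,
               delta = opened - base$atp_yield)
  })
  do.call(rbind, rows)
}

#' Run the full yield grid
#'
#' Computes the maximal ATP yield over
#' {site} x {condition} x {amino acids} x {model}, where `models` is a
#' named list of coupled models (e.g. `control` and `retina_specific`).
#' A failing cell is recorded with status `"error"`; the run continues.
#'
#' @param models named list of coupled `metabolic_model`s.
#' @param config constraint configuration.
#' @param sites,conditions,amino_acids grid axes.
#' @param objective,map as in [max_atp()].
#' @return a `yield_grid` data.frame: `model_tag`, `site`, `condition`,
#'   `amino_acids`, `status`, `atp_yield`.
#' @export
run_grid <- function(models, config = default_constraint_config(),
                     sites = c("perifovea", "fovea"),
                     conditions = c("light", "dark"),
                     amino_acids = c(FALSE, TRUE),
                     objective = "ATPM_PR", map = toy_metabolite_map()) {
  stopifnot(is.list(models), !is.null(names(models)))
  grid <- expand.grid(model_tag = names(models), site = sites,
                      condition = conditions, amino_acids = amino_acids,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    r <- tryCatch({
      cs <- build_constraint_set(g$site, g$condition, config,
                                 amino_acids = g$amino_acids)
      max_atp(models[[g$model_tag]], cs, objective = objective, map = map,
              model_tag = g$model_tag)
    }, error = function(e) NULL)
    data.frame(g,
               status = if (is.null(r)) "error" else r$status,
               atp_yield = if (is.null(r)) NA_real_ else r$atp_yield)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$model_tag, out$site, out$condition, out$amino_acids), ]
  rownames(out) <- NULL
  class(out) <- c("yield_grid", "data.frame")
  out
}

#' Write a yield grid as TSV
#' @param grid a `yield_grid`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_grid_tsv <- function(grid, path) {
  utils::write.table(as.data.frame(grid), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

md5_of <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 12), f)
  unname(tools::md5sum(f))
}

#' Deterministic run manifest for a yield grid
#'
#' Hashes the configuration and the grid results so two runs of the same
#' pipeline can be compared for reproducibility. No timestamps: the
#' manifest is a pure function of its inputs.
#'
#' @param grid a `yield_grid`.
#' @param config the constraint configuration used.
#' @return list with `config_hash`, `results_hash`, `n_cells`,
#'   `n_feasible`.
#' @export
run_manifest <- function(grid, config = default_constraint_config()) {
  list(config_hash = md5_of(config),
       results_hash = md5_of(as.data.frame(grid)),
       n_cells = nrow(grid),
       n_feasible = sum(grid$status == "optimal"))
}

#' Write a run manifest as JSON
#' @param manifest from [run_manifest()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
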