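# Blood-tissue exchange constraints for {fovea, perifovea} x {light, dark},
# assembled from printed physiological constants: macaque outer-retina
# oxygen uptake from oxygen-profile measurements, the inner-retina share of
# perifoveal PR oxygen, an RPE oxygen add-on from culture respirometry,
# glucose/lactate per-area fluxes derived from cat arteriovenous
# differences, and amino-acid uptake bounds scaled from plasma
# concentrations. All fluxes in pmol.s-1.mm-2.

#' Split total photoreceptor oxygen uptake between the two circulations
#'
#' The inner-retina (retinal circulation) share of perifoveal PR oxygen
#' uptake enters at the PR-side interface; the remainder comes through the
#' choriocapillaris at the RPE-side interface. The sum is conserved exactly.
#'
#' @param total_uptake total PR oxygen uptake (pmol.s-1.mm-2).
#' @param inner_retina_fraction fraction supplied by the retinal
#'   circulation, in `[0, 1)` (0.11 in light, 0.15 in dark at the
#'   perifovea; 0 at the fovea, which has no retinal circulation).
#' @return named numeric `c(e_RPE = ..., e_PR = ...)`.
#' @export
split_oxygen <- function(total_uptake, inner_retina_fraction) {
  if (inner_retina_fraction < 0 || inner_retina_fraction >= 1) {
    stop("inner_retina_fraction must be in [0, 1)")
  }
  e_pr <- total_uptake * inner_retina_fraction
  c(e_RPE = total_uptake - e_pr, e_PR = e_pr)
}

#' Convert an RPE oxygen consumption rate to a per-area flux
#'
#' @param rate oxygen consumption in pmol.min-1 (as reported by plate
#'   respirometry).
#' @param area culture surface area in mm2.
#' @return flux in pmol.s-1.mm-2.
#' @export
rpe_oxygen_per_area <- function(rate, area) {
  if (rate <= 0 || area <= 0) stop("rate and area must be positive")
  rate / 60 / area
}

#' Area of an equilateral triangle
#'
#' Helper for per-area fluxes measured on triangular RPE patches:
#' `A = (sqrt(3)/4) a^2`.
#'
#' @param a side length (mm).
#' @return area in mm2.
#' @export
equilateral_area <- function(a) {
  if (any(a <= 0)) stop("side length must be positive")
  sqrt(3) / 4 * a^2
}

#' Fick's-law parameters for transchoroidal oxygen diffusion
#'
#' @param D oxygen diffusion coefficient in cm2.s-1 (default `1.97e-5`).
#' @param alpha oxygen solubility in pmol.mm-3.mmHg-1 (default `1.38`,
#'   i.e. ~1.38 uM per mmHg).
#' @param delta_P oxygen tension difference across the path in mmHg
#'   (default 100: choriocapillaris tension against an assumed zero at the
#'   inner aspect of the inner-segment/ellipsoid-zone line).
#' @param f choriocapillaris area fraction available for exchange
#'   (default 0.7).
#' @param L diffusion distance in micrometres (58 at the perifovea, 77 at
#'   the foveal centre, from OCT).
#' @return a `fick_parameters` list.
#' @export
fick_params <- function(D = 1.97e-5, alpha = 1.38, delta_P = 100, f = 0.7,
                        L = 58) {
  vals <- c(D = D, alpha = alpha, delta_P = delta_P, f = f, L = L)
  if (any(vals <= 0)) {
    stop("non-positive Fick parameter: ",
         paste(names(vals)[vals <= 0], collapse = ", "))
  }
  structure(as.list(vals), class = "fick_parameters")
}

#' Theoretical maximum oxygen flux by Fick's first law
#'
#' Evaluates `J = D * alpha * delta_P * f / L` after canonicalising units
#' to mm and seconds (D arrives in cm2.s-1, L in um).
#'
#' @param p a [fick_params()] object.
#' @return flux in pmol.s-1.mm-2.
#' @export
fick_max_flux <- function(p = fick_params()) {
  stopifnot(inherits(p, "fick_parameters"))
  D_mm2 <- p$D * 100      # cm2 -> mm2
  L_mm <- p$L / 1000      # um -> mm
  if (L_mm == 0) stop("diffusion distance must be positive")
  D_mm2 * p$alpha * p$delta_P * p$f / L_mm
}

#' Cat eye geometry for arteriovenous-difference conversion
#'
#' @param radius eye radius in mm (default 11).
#' @param retina_fraction proportion of the eye surface occupied by retina
#'   (default 0.65).
#' @return a `cat_geometry` list.
#' @export
cat_geometry <- function(radius = 11, retina_fraction = 0.65) {
  if (radius <= 0) stop("radius must be positive")
  if (retina_fraction <= 0 || retina_fraction > 1) {
    stop("retina_fraction must be in (0, 1]")
  }
  structure(list(radius = radius, retina_fraction = retina_fraction),
            class = "cat_geometry")
}

#' Retinal surface area of the spherical cat eye
#' @param geom a [cat_geometry()].
#' @return area in mm2 (988.3 for the defaults).
#' @export
retina_area <- function(geom = cat_geometry()) {
  geom$retina_fraction * 4 * pi * geom$radius^2
}

#' Convert a whole-retina arteriovenous difference to a per-area flux
#'
#' @param av_difference whole-retina uptake or release in pmol.s-1.
#' @param geom a [cat_geometry()].
#' @return flux in pmol.s-1.mm-2.
#' @export
av_to_flux <- function(av_difference, geom = cat_geometry()) {
  av_difference / retina_area(geom)
}

#' Transfer a cat-derived flux to the macaque via the oxygen ratio
#'
#' Keeps the ratio of a metabolite's flux to the oxygen flux constant
#' between species: `macaque_flux = macaque_o2 * cat_flux / cat_o2`.
#'
#' @param cat_metabolite_flux per-area flux of the metabolite in the cat.
#' @param cat_o2_flux per-area oxygen flux in the cat (must be positive).
#' @param macaque_o2_flux per-area oxygen flux in the macaque.
#' @return scaled flux in pmol.s-1.mm-2.
#' @export
scale_by_oxygen_ratio <- function(cat_metabolite_flux, cat_o2_flux,
                                  macaque_o2_flux) {
  if (cat_o2_flux <= 0) stop("cat oxygen flux must be positive")
  macaque_o2_flux * cat_metabolite_flux / cat_o2_flux
}

#' Read a plasma concentration table
#'
#' TSV with columns `metabolite` and `concentration_uM`; must contain a
#' positive glucose entry. The table shipped with the package
#' (`plasma_concentrations.tsv`) is a synthetic stand-in with
#' database-typical values.
#'
#' @param path TSV file; defaults to the shipped table.
#' @return named numeric vector of concentrations in uM.
#' @export
read_plasma_table <- function(path = system.file("extdata",
                                                 "plasma_concentrations.tsv",
                                                 package = "retbudget")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("metabolite", "concentration_uM") %in% names(tab))) {
    stop("plasma table needs columns metabolite, concentration_uM")
  }
  conc <- stats::setNames(tab$concentration_uM, tab$metabolite)
  if (!"glucose" %in% names(conc) || conc["glucose"] <= 0) {
    stop("plasma table must contain a positive glucose concentration")
  }
  conc
}

#' Amino-acid uptake bounds scaled from plasma concentrations
#'
#' With no arteriovenous data for amino acids, each amino acid's uptake
#' bound is set relative to the glucose bound in the ratio of its plasma
#' concentration to that of glucose:
#' `bound(aa) = glucose_bound * C_aa / C_glucose`.
#'
#' @param glucose_uptake_bound glucose uptake bound (pmol.s-1.mm-2).
#' @param plasma named concentration vector from [read_plasma_table()].
#' @param amino_acids which amino acids to include (default: every
#'   non-glucose entry); entries missing from the table are skipped with a
#'   warning.
#' @return named numeric vector of uptake bounds.
#' @export
amino_acid_bounds <- function(glucose_uptake_bound, plasma,
                              amino_acids = setdiff(names(plasma), "glucose")) {
  missing_aa <- setdiff(amino_acids, names(plasma))
  if (length(missing_aa)) {
    warning("not in plasma table, skipped: ",
            paste(missing_aa, collapse = ", "))
    amino_acids <- intersect(amino_acids, names(plasma))
  }
  glucose_uptake_bound * plasma[amino_acids] / plasma[["glucose"]]
}

#' Default constraint configuration
#'
#' Oxygen values are the printed macaque oxygen-profile estimates; the
#' inner-retina fractions and RPE add-on are likewise printed constants.
#' The per-area glucose and lactate fluxes are synthetic stand-ins for the
#' supplementary-table values (which derive from cat arteriovenous data),
#' chosen once on physiological grounds; override them with measured values
#' when available. `interface_o2_transfer` is a placeholder for the fixed
#' interface oxygen transfer (supplementary material); `NA` leaves the
#' transfer unconstrained.
#'
#' @return nested list with sections `oxygen`, `glucose_lactate`,
#'   `amino_acids`, `fick`, `cat_geometry`.
#' @export
default_constraint_config <- function() {
  list(
    oxygen = list(
      macaque = list(
        perifovea = c(light = 2.46, dark = 3.74),
        fovea = c(light = 2.34, dark = 2.72)),
      inner_retina_fraction = c(light = 0.11, dark = 0.15),
      rpe_addon = 0.30,
      interface_transfer = NA_real_),
    glucose_lactate = list(
      # synthetic stand-ins for the AV-derived per-area fluxes
      glucose_uptake = list(perifovea = c(light = 2.0, dark = 4.6),
                            fovea = c(light = 1.7, dark = 3.3)),
      lactate_export = list(perifovea = c(light = 4.75, dark = 8.2),
                            fovea = c(light = 3.8, dark = 5.8))),
    amino_acids = list(
      plasma_table = system.file("extdata", "plasma_concentrations.tsv",
                                 package = "retbudget")),
    fick = list(D = 1.97e-5, alpha = 1.38, delta_P = 100, f = 0.7,
                L = c(perifovea = 58, fovea = 77)),
    cat_geometry = list(radius = 11, retina_fraction = 0.65)
  )
}

# fetch a nested config entry, erroring with the dotted key name
cfg_get <- function(config, ...) {
  path <- c(...)
  x <- config
  for (k in path) {
    if (is.null(x[[k]])) stop("missing config key: ",
                              paste(path, collapse = "."))
    x <- x[[k]]
  }
  x
}

#' Read a TOML-style constraint configuration file
#'
#' Supports the subset used by the shipped config: `[section]` headers,
#' `key = value` pairs with numeric, boolean or quoted-string scalars, and
#' `#` comments. Dotted keys (`a.b = 1`) nest below the current section.
#'
#' @param path configuration file.
#' @return nested list mirroring [default_constraint_config()].
#' @export
read_constraint_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- character(0)
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- strsplit(gsub("^\\[|\\]$", "", ln), ".", fixed = TRUE)[[1]]
      next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("cannot parse config line: ", ln)
    key <- strsplit(trimws(kv[1]), ".", fixed = TRUE)[[1]]
    val <- trimws(paste(kv[-1], collapse = "="))
    val <- if (grepl('^".*"$', val)) {
      gsub('^"|"$', "", val)
    } else if (tolower(val) %in% c("true", "false")) {
      as.logical(val)
    } else if (tolower(val) %in% c("na", "nan")) {
      NA_real_
    } else {
      as.numeric(val)
    }
    path_keys <- c(section, key)
    out <- cfg_assign(out, path_keys, val)
  }
  out
}

cfg_assign <- function(x, keys, val) {
  if (length(keys) == 1L) {
    x[[keys]] <- val
    return(x)
  }
  if (is.null(x[[keys[1]]])) x[[keys[1]]] <- list()
  x[[keys[1]]] <- cfg_assign(x[[keys[1]]], keys[-1], val)
  x
}

#' Build the exchange-constraint set for one site and condition
#'
#' Assembles named exchange bounds at the two circulation interfaces:
#' oxygen split between the choriocapillaris (RPE-side) and retinal
#' circulation (PR-side) at the perifovea or delivered entirely RPE-side at
#' the fovea (which has no retinal circulation), with the RPE oxygen add-on
#' applied to the RPE-side bound; a glucose uptake cap and a lactate export
#' floor at the RPE-side interface; amino-acid uptake bounds (plasma-scaled)
#' when enabled; water free in both directions; every other metabolite free
#' to leave but not to enter.
#'
#' @param site `"fovea"` or `"perifovea"`.
#' @param condition `"light"` or `"dark"`.
#' @param config configuration list, see [default_constraint_config()].
#' @param amino_acids logical; include amino-acid uptake bounds.
#' @return a `constraint_set`.
#' @export
build_constraint_set <- function(site = c("perifovea", "fovea"),
                                 condition = c("light", "dark"),
                                 config = default_constraint_config(),
                                 amino_acids = FALSE) {
  site <- match.arg(site)
  condition <- match.arg(condition)

  o2_total <- cfg_get(config, "oxygen", "macaque", site)[[condition]]
  addon <- cfg_get(config, "oxygen", "rpe_addon")
  if (site == "perifovea") {
    frac <- cfg_get(config, "oxygen", "inner_retina_fraction")[[condition]]
    sp <- split_oxygen(o2_total, frac)
  } else {
    sp <- split_oxygen(o2_total, 0)  # no retinal circulation in the foveal pit
  }
  rows <- data.frame(
    interface = c("e_RPE", "e_PR"),
    metabolite = "oxygen",
    uptake_max = c(sp[["e_RPE"]] + addon, sp[["e_PR"]]),
    export_min = 0, export_max = 0,
    stringsAsFactors = FALSE)

  glc <- cfg_get(config, "glucose_lactate", "glucose_uptake", site)[[condition]]
  lac <- cfg_get(config, "glucose_lactate", "lactate_export", site)[[condition]]
  rows <- rbind(rows, data.frame(
    interface = c("e_RPE", "e_RPE"),
    metabolite = c("glucose", "lactate"),
    uptake_max = c(glc, 0),
    export_min = c(0, lac),
    export_max = c(Inf, Inf)))

  if (amino_acids) {
    plasma_path <- tryCatch(cfg_get(config, "amino_acids", "plasma_table"),
                            error = function(e) NULL)
    plasma <- if (is.null(plasma_path)) read_plasma_table() else
      read_plasma_table(plasma_path)
    aab <- amino_acid_bounds(glc, plasma)
    aa_if <- if (site == "perifovea") c("e_RPE", "e_PR") else "e_RPE"
    for (ifc in aa_if) {
      rows <- rbind(rows, data.frame(
        interface = ifc, metabolite = names(aab),
        uptake_max = unname(aab), export_min = 0, export_max = Inf))
    }
  }

  rows <- rbind(rows, data.frame(
    interface = c("e_RPE", "e_PR"),
    metabolite = "water",
    uptake_max = Inf, export_min = 0, export_max = Inf))

  stopifnot(all(rows$uptake_max >= 0 | is.infinite(rows$uptake_max)),
            all(rows$export_min >= 0))
  if (site == "fovea") {
    o2pr <- rows$uptake_max[rows$interface == "e_PR" &
                              rows$metabolite == "oxygen"]
    stopifnot(o2pr == 0)
  }

  structure(list(site = site, condition = condition,
                 amino_acids_enabled = amino_acids,
                 bounds = rows,
                 interface_o2_transfer = cfg_get(config, "oxygen",
                                                 "interface_transfer")),
            class = "constraint_set")
}

#' @export
print.constraint_set <- function(x, ...) {
  cat("<constraint_set> ", x$site, "/", x$condition,
      if (x$amino_acids_enabled) " (+amino acids)" else "", "\n", sep = "")
  b <- x$bounds
  b$uptake_max <- round(b$uptake_max, 2)  # full precision kept internally
  print(b, row.names = FALSE)
  invisible(x)
}

#' Metabolite name mapping for the toy network
#'
#' Maps the constraint set's metabolite names onto the toy network's base
#' metabolite ids. Amino acids are pooled onto the generic `aa` metabolite
#' by [apply_constraints()].
#'
#' @return named character vector (constraint name -> model base name).
#' @export
toy_metabolite_map <- function() {
  c(oxygen = "o2", glucose = "glc", lactate = "lac", water = "h2o",
    fatty_acid = "fa")
}

#' Apply a constraint set to a coupled model
#'
#' Rewrites the bounds of the exchange reactions at the two circulation
#' interfaces. Constraint metabolite names are translated to model base
#' names through `map`; names not in `map` (the amino acids) are pooled
#' onto `aa_pool` with their uptake bounds summed. Exchanges not named by
#' the constraint set are left free to export but closed to uptake.
#'
#' @param model a coupled `metabolic_model` with interface compartments
#'   `e_RPE` and `e_PR`.
#' @param cs a `constraint_set`.
#' @param map named character vector (constraint name -> base metabolite
#'   name), see [toy_metabolite_map()].
#' @param aa_pool base metabolite name of the pooled amino-acid species
#'   (`NULL` to require explicit mapping).
#' @param default_ub upper bound used for "free" export.
#' @return the constrained model.
#' @export
apply_constraints <- function(model, cs, map = toy_metabolite_map(),
                              aa_pool = "aa", default_ub = 1000) {
  stopifnot(inherits(cs, "constraint_set"))
  b <- cs$bounds
  base <- ifelse(b$metabolite %in% names(map),
                 unname(map[b$metabolite]),
                 if (is.null(aa_pool)) NA_character_ else aa_pool)
  if (anyNA(base)) {
    stop("no mapping for constraint metabolites: ",
         paste(unique(b$metabolite[is.na(base)]), collapse = ", "))
  }
  # pool rows landing on the same (interface, base metabolite)
  key <- paste(b$interface, base, sep = "|")
  agg <- lapply(split(seq_len(nrow(b)), key), function(i) {
    c(uptake = sum(b$uptake_max[i]), emin = sum(b$export_min[i]),
      emax = max(b$export_max[i]))
  })

  ex <- exchange_reactions(model, compartment = c("e_RPE", "e_PR"))
  if (!nrow(ex)) stop("model has no exchange reactions at e_RPE / e_PR")
  for (k in seq_len(nrow(ex))) {
    met_base <- sub(paste0("_", ex$compartment[k], "$"), "", ex$metabolite[k])
    met_base <- sub("_e$", "", met_base)
    kk <- paste(ex$compartment[k], met_base, sep = "|")
    if (kk %in% names(agg)) {
      u <- agg[[kk]]
      lo <- -min(u[["uptake"]], .lp_big)
      hi <- min(u[["emax"]], default_ub)
      if (u[["emin"]] > 0) lo <- u[["emin"]]
      if (is.infinite(u[["uptake"]])) lo <- -default_ub
      if (lo > hi) hi <- max(hi, lo)
    } else {
      lo <- 0; hi <- default_ub  # free to leave, closed to uptake
    }
    if (ex$coefficient[k] > 0) {  # written as (nothing) -> met: flip signs
      tmp <- lo; lo <- -hi; hi <- -tmp
    }
    model <- set_bounds(model, ex$reaction[k], lower = lo, upper = hi)
  }

  if (!is.na(cs$interface_o2_transfer)) {
    # fixed interface oxygen transfer (supplementary-table constant)
    cand <- grep("^T_o2_.*_PR_RPE$|^T_o2_PR_RPE$", model$rxns$id, value = TRUE)
    for (rid in cand) {
      model <- set_bounds(model, rid, lower = cs$interface_o2_transfer,
                          upper = cs$interface_o2_transfer)
    }
  }
  model
}
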