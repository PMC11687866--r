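# Age/eccentricity analysis: calibration of OCTA flow deficits against
# histological choriocapillaris (CC) density, eccentricity interpolation,
# rod density fits, rod inner-segment (IS) cross-sectional area, and the
# combined fractional change in nutrient exchange per rod.

#' Fit the flow-deficit to CC-density calibration line
#'
#' Ordinary least squares of CC density (%) on OCTA flow deficit (%),
#' matched by decade. The fitted line translates flow-deficit imaging data
#' into the anatomical area-fraction measure of the CC.
#'
#' @param flow_deficit flow-deficit percentages, or a data.frame with
#'   columns `flow_deficit_pct` and `cc_density_pct`.
#' @param cc_density CC density percentages (omit when a data.frame is
#'   given).
#' @return a `cc_calibration`: list with `slope`, `intercept`, `adj_r2`
#'   and the underlying `lm` fit. Has `coef`, `predict` and `print`
#'   methods.
#' @export
fit_calibration <- function(flow_deficit, cc_density = NULL) {
  if (is.data.frame(flow_deficit)) {
    cc_density <- flow_deficit$cc_density_pct
    flow_deficit <- flow_deficit$flow_deficit_pct
  }
  if (length(flow_deficit) < 3) stop("need at least 3 calibration points")
  if (length(flow_deficit) != length(cc_density)) stop("length mismatch")
  if (stats::sd(flow_deficit) == 0) stop("zero variance in flow deficit")
  fit <- stats::lm(cc_density ~ flow_deficit)
  s <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 adj_r2 = s$adj.r.squared, fit = fit),
            class = "cc_calibration")
}

#' @export
print.cc_calibration <- function(x, ...) {
  cat("<cc_calibration> density = ", format(x$intercept, digits = 4),
      ifelse(x$slope < 0, " - ", " + "),
      format(abs(x$slope), digits = 4), " * flow_deficit (adj R2 = ",
      format(x$adj_r2, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' @export
coef.cc_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.cc_calibration <- function(object, newdata, ...) {
  flow_deficit_to_density(object, newdata)
}

#' Convert a flow deficit to a CC density through the calibration
#'
#' @param cal a `cc_calibration`.
#' @param fd flow deficit (%), vectorised.
#' @return CC density (%), clamped to `[0, 100]`.
#' @export
flow_deficit_to_density <- function(cal, fd) {
  stopifnot(inherits(cal, "cc_calibration"))
  pmin(pmax(cal$intercept + cal$slope * fd, 0), 100)
}

#' Eccentricity profile with linear interpolation
#'
#' Samples of a quantity along retinal eccentricity for one age group.
#' Between samples the profile is piecewise linear; beyond either end it is
#' constant (the most central value is assumed to hold to the fovea, the
#' most peripheral value further to the periphery).
#'
#' @param eccentricity strictly increasing eccentricities in mm.
#' @param values sampled values.
#' @param age_group label.
#' @return an `eccentricity_profile`.
#' @export
eccentricity_profile <- function(eccentricity, values, age_group = "") {
  if (length(eccentricity) == 0) stop("profile is empty")
  if (any(diff(eccentricity) <= 0)) {
    stop("eccentricities must be strictly increasing")
  }
  if (length(eccentricity) != length(values)) stop("length mismatch")
  structure(list(eccentricity = eccentricity, values = values,
                 age_group = age_group), class = "eccentricity_profile")
}

#' Interpolate an eccentricity profile
#'
#' @param profile an `eccentricity_profile`.
#' @param ecc eccentricities (mm) to evaluate at, vectorised.
#' @return interpolated values (constant extrapolation beyond the ends).
#' @export
interpolate_profile <- function(profile, ecc) {
  stopifnot(inherits(profile, "eccentricity_profile"))
  if (length(profile$eccentricity) == 1L) {
    return(rep(profile$values, length(ecc)))
  }
  stats::approx(profile$eccentricity, profile$values, xout = ecc,
                rule = 2)$y
}

#' Polynomial fit to a rod density profile
#'
#' Least-squares polynomial in eccentricity, enabling arithmetic between
#' density profiles sampled at different eccentricities. Predictions are
#' clamped to non-negative densities.
#'
#' @param eccentricity sample eccentricities (mm).
#' @param density rod densities (rods per mm2).
#' @param degree polynomial degree (default 5).
#' @return a `rod_density_fit` with `coefficients`, `rmse` and `predict`
#'   / `print` methods.
#' @export
fit_rod_density <- function(eccentricity, density, degree = 5) {
  if (length(eccentricity) < degree + 2) {
    stop("need at least degree + 2 samples")
  }
  fit <- if (degree == 0) {
    stats::lm(density ~ 1)
  } else {
    stats::lm(density ~ stats::poly(eccentricity, degree, raw = TRUE))
  }
  pred <- stats::fitted(fit)
  structure(list(coefficients = unname(stats::coef(fit)),
                 degree = degree,
                 rmse = sqrt(mean((density - pred)^2)),
                 range = range(eccentricity), fit = fit),
            class = "rod_density_fit")
}

#' @export
print.rod_density_fit <- function(x, ...) {
  cat("<rod_density_fit> degree ", x$degree, ", RMSE ",
      format(x$rmse, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
predict.rod_density_fit <- function(object, newdata, ...) {
  X <- outer(newdata, 0:object$degree, `^`)
  pmax(as.numeric(X %*% object$coefficients), 0)
}

#' Rod inner-segment cross-sectional area
#'
#' The retinal plane not occupied by cone inner segments is shared by the
#' rods, so the IS cross-section per rod is
#' `(1 - cone_area_fraction) / rod_density`. As rods are lost with age the
#' remaining rods enlarge, capturing more of the nutrient exchange.
#'
#' @param rod_density rods per mm2 (must be positive; the central zone
#'   where cones dominate is excluded from this analysis).
#' @param cone_area_fraction fraction of the plane occupied by cones, in
#'   `[0, 1)`.
#' @return IS area per rod in mm2, vectorised.
#' @export
rod_is_area <- function(rod_density, cone_area_fraction) {
  if (any(rod_density <= 0)) stop("rod density must be positive")
  if (any(cone_area_fraction < 0 | cone_area_fraction >= 1)) {
    stop("cone area fraction must be in [0, 1)")
  }
  (1 - cone_area_fraction) / rod_density
}

#' Combined fractional change in nutrient exchange per rod
#'
#' The CC area fraction and the rod IS cross-section both gate
#' one-dimensional exchange between the CC and the rods, so their
#' fractional changes multiply.
#'
#' @param cc_frac fractional change in CC density vs baseline.
#' @param rod_area_frac fractional change in rod IS area vs baseline.
#' @return the product, vectorised.
#' @export
fractional_flux_change <- function(cc_frac, rod_area_frac) {
  if (any(cc_frac <= 0) || any(rod_area_frac <= 0)) {
    stop("fractional changes must be positive")
  }
  cc_frac * rod_area_frac
}

#' Supply/demand budget ratio
#'
#' @param supply per-condition ATP supply estimates (pmol.s-1.mm-2).
#' @param demand matching ATP demand estimates (positive).
#' @return a `budget_ratio`: `overall` = mean(supply)/mean(demand), plus
#'   `per_condition` ratios. Printed to two significant figures.
#' @export
budget_ratio <- function(supply, demand) {
  if (length(supply) != length(demand)) stop("length mismatch")
  if (any(demand <= 0)) stop("demand must be positive")
  structure(list(overall = mean(supply) / mean(demand),
                 per_condition = supply / demand),
            class = "budget_ratio")
}

#' @export
print.budget_ratio <- function(x, ...) {
  cat("<budget_ratio> supply/demand = ", signif(x$overall, 2), "\n", sep = "")
  cat("  per condition:", paste(signif(x$per_condition, 3), collapse = ", "),
      "\n")
  invisible(x)
}

#' Combined aging profiles of nutrient exchange per rod
#'
#' Runs the full aging analysis: converts OCTA flow deficits to CC
#' densities through the calibration, interpolates them over the rod
#' table's eccentricity grid, fits rod density polynomials per age group,
#' derives rod IS areas, and combines the fractional changes. The CC
#' baseline is the mean CC density of the youngest age group; the rod
#' baseline is the named baseline group's IS area at the same
#' eccentricity. Eccentricities below `min_ecc` are excluded (cones
#' dominate centrally and the rod estimates are unreliable there).
#'
#' @param octa data.frame `age_group`, `eccentricity_mm`,
#'   `flow_deficit_pct`.
#' @param calibration a `cc_calibration`, or a data.frame of calibration
#'   pairs passed to [fit_calibration()].
#' @param rods data.frame `age_group`, `eccentricity_mm`,
#'   `rod_density_per_mm2`.
#' @param cones data.frame `eccentricity_mm`, `cone_area_fraction`.
#' @param baseline_rod_group age-group label used as the rod baseline
#'   (default `"25"`).
#' @param baseline_cc_group CC baseline group (default: the first group in
#'   the OCTA table, i.e. the youngest).
#' @param min_ecc central exclusion radius in mm (default 0.5).
#' @param degree rod polynomial degree (default 5).
#' @return an `aging_profiles` data.frame: `age_group`, `eccentricity_mm`,
#'   `cc_density_pct`, `rod_density_per_mm2`, `cone_area_fraction`,
#'   `rod_is_area_mm2`, `frac_cc`, `frac_rod_area`, `frac_combined`.
#' @export
aging_profiles <- function(octa, calibration, rods, cones,
                           baseline_rod_group = "25",
                           baseline_cc_group = NULL,
                           min_ecc = 0.5, degree = 5) {
  if (!inherits(calibration, "cc_calibration")) {
    calibration <- fit_calibration(calibration)
  }
  groups <- unique(octa$age_group)
  if (is.null(baseline_cc_group)) baseline_cc_group <- groups[1]
  if (!baseline_rod_group %in% rods$age_group) {
    stop("baseline rod group not in rod table: ", baseline_rod_group)
  }

  ecc <- sort(unique(rods$eccentricity_mm))
  ecc <- ecc[ecc >= min_ecc]
  if (!length(ecc)) stop("no eccentricities at or beyond min_ecc")

  cc_profile <- function(g) {
    sub <- octa[octa$age_group == g, ]
    sub <- sub[order(sub$eccentricity_mm), ]
    dens <- flow_deficit_to_density(calibration, sub$flow_deficit_pct)
    eccentricity_profile(sub$eccentricity_mm, dens, g)
  }
  cc_base <- mean(cc_profile(baseline_cc_group)$values)

  rod_fit <- function(g) {
    sub <- rods[rods$age_group == g & rods$eccentricity_mm >= min_ecc, ]
    fit_rod_density(sub$eccentricity_mm, sub$rod_density_per_mm2, degree)
  }
  base_fit <- rod_fit(baseline_rod_group)
  cone_prof <- eccentricity_profile(cones$eccentricity_mm,
                                    cones$cone_area_fraction)
  cone_f <- interpolate_profile(cone_prof, ecc)
  base_area <- rod_is_area(predict(base_fit, ecc), cone_f)

  out <- do.call(rbind, lapply(groups, function(g) {
    cc <- interpolate_profile(cc_profile(g), ecc)
    rod_d <- predict(rod_fit(g), ecc)
    area <- rod_is_area(rod_d, cone_f)
    frac_cc <- cc / cc_base
    frac_rod <- area / base_area
    data.frame(age_group = g, eccentricity_mm = ecc,
               cc_density_pct = cc, rod_density_per_mm2 = rod_d,
               cone_area_fraction = cone_f, rod_is_area_mm2 = area,
               frac_cc = frac_cc, frac_rod_area = frac_rod,
               frac_combined = fractional_flux_change(frac_cc, frac_rod),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("aging_profiles", "data.frame")
  out
}

#' Plot aging profiles
#'
#' Base-graphics panel of fractional CC change (solid) and combined
#' CC-by-rod-area change (dotted) against eccentricity, one colour per age
#' group.
#'
#' @param x an `aging_profiles` data.frame.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.aging_profiles <- function(x, ...) {
  groups <- unique(x$age_group)
  cols <- grDevices::hcl.colors(max(3, length(groups)), "Dark 3")
  ecc <- sort(unique(x$eccentricity_mm))
  cc <- sapply(groups, function(g) x$frac_cc[x$age_group == g])
  comb <- sapply(groups, function(g) x$frac_combined[x$age_group == g])
  graphics::matplot(ecc, cc, type = "l", lty = 1, col = cols,
                    xlab = "eccentricity (mm)",
                    ylab = "fractional change vs baseline",
                    ylim = range(c(cc, comb)), ...)
  graphics::matlines(ecc, comb, lty = 3, col = cols)
  graphics::abline(h = 1, col = "grey")
  graphics::legend("topleft", legend = groups, col = cols[seq_along(groups)],
                   lty = 1, bty = "n", title = "age group")
  invisible(x)
}
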