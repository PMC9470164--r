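#' Convert a lipid mole fraction to an absolute surface density
#'
#' Divides the mole fraction by the area footprint of one phospholipid
#' (default 0.72 nm^2, the DOPC footprint), giving lipids per um^2 of
#' membrane with no leaflet factor: a 4 mole-percent PIP composition
#' yields 55,556 lipids/um^2.
#'
#' @param mole_fraction lipid mole fraction in `[0, 1]`.
#' @param area_per_lipid lipid footprint, nm^2.
#' @return Surface density, lipids/um^2 (vectorized over
#'   `mole_fraction`).
#' @export
lipid_density <- function(mole_fraction, area_per_lipid = 0.72) {
  stopifnot(all(mole_fraction >= 0), all(mole_fraction <= 1))
  .check_pos(area_per_lipid, "area_per_lipid")
  mole_fraction / (area_per_lipid * 1e-6)  # nm^2 -> um^2
}

#' Build a fluorescence-to-surface-density calibration curve
#'
#' Least-squares line through standards of known surface density (e.g. a
#' fluorescent lipid titrated into supported bilayers, with densities
#' from the known mole fractions, or an FCS-calibrated protein series).
#' When the probe of interest carries a different fluorophore than the
#' standard, a unitless scaling factor - the ratio of the two dyes'
#' solution brightness slopes - converts the standard's slope to the
#' probe scale.  The inverse mapping is
#' `density(I) = (I - intercept) / (slope * scaling_factor)`.
#'
#' @param densities standard surface densities, molecules/um^2
#'   (>= 3 points, strictly increasing).
#' @param intensities mean intensities of the standards, arbitrary units.
#' @param probe_solution_slope,standard_solution_slope solution
#'   brightness slopes of the probe dye and the standard dye (same
#'   arbitrary units); their ratio is the scaling factor.  Defaults give
#'   scaling factor 1 (identical dyes).
#' @return Object of class `calibration_curve` with `slope`,
#'   `intercept`, `scaling_factor` and the standards.
#' @seealso [predict.calibration_curve()], [intensity_from_density()]
#' @export
build_calibration <- function(densities, intensities,
                              probe_solution_slope = 1,
                              standard_solution_slope = 1) {
  stopifnot(length(densities) == length(intensities),
            length(densities) >= 3L)
  if (any(diff(order(densities)) <= 0) || any(diff(sort(densities)) == 0))
    stop("standard densities must be distinct")
  if (any(diff(densities[order(densities)]) <= 0) ||
      !all(diff(intensities[order(densities)]) > 0))
    stop("standard intensities must increase monotonically with density")
  scaling_factor <- probe_solution_slope / standard_solution_slope
  if (scaling_factor <= 0) stop("scaling factor must be > 0")
  fit <- lm(intensities ~ densities)
  slope <- unname(coef(fit)[2])
  if (slope <= 0) stop("calibration slope must be > 0")
  out <- list(slope = slope, intercept = unname(coef(fit)[1]),
              scaling_factor = scaling_factor,
              standard_densities = densities,
              standard_intensities = intensities)
  class(out) <- "calibration_curve"
  out
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "Calibration: I = %.4g * density + %.4g (scaling factor %.4g, %d standards)\n",
    x$slope, x$intercept, x$scaling_factor,
    length(x$standard_densities)))
  invisible(x)
}

#' Convert measured intensities to surface densities
#'
#' @param object a [build_calibration()] curve.
#' @param intensity measured intensities, arbitrary units.
#' @param ... unused.
#' @return Surface densities, molecules/um^2.
#' @export
predict.calibration_curve <- function(object, intensity, ...) {
  (intensity - object$intercept) / (object$slope * object$scaling_factor)
}

#' Forward-map surface densities to expected intensities
#'
#' Inverse of [predict.calibration_curve()]; useful for round-trip
#' checks and for synthesizing titration intensities.
#'
#' @param curve a [build_calibration()] curve.
#' @param density surface densities, molecules/um^2.
#' @return Expected intensities, arbitrary units.
#' @export
intensity_from_density <- function(curve, density) {
  density * curve$slope * curve$scaling_factor + curve$intercept
}

#' Fit a cooperative (Hill) membrane-binding isotherm
#'
#' Weighted nonlinear least squares fit of the concerted-cooperativity
#' isotherm `rho(c) = Bmax * c^n_H / (Kd^n_H + c^n_H)` to a titration of
#' solution concentration vs calibrated surface density.  Weights are
#' inverse-variance when replicate SDs are supplied, otherwise uniform.
#' When the maximum observed density is below 70% of the fitted
#' saturation the fit is flagged as extrapolated.
#'
#' @param concentrations solution concentrations, nM (>= 5 points
#'   spanning both sides of half-saturation).
#' @param densities surface densities, molecules/um^2.
#' @param sd optional replicate standard deviations (same length).
#' @param fix_n_H optional fixed Hill coefficient (e.g. 1 for the
#'   non-cooperative reference model); `NULL` (default) fits `n_H`.
#' @return Object of class `hill_fit`: `Bmax`, `Kd`, `n_H`, standard
#'   errors, residuals, `extrapolated` flag and the data.
#' @export
fit_hill <- function(concentrations, densities, sd = NULL, fix_n_H = NULL) {
  stopifnot(length(concentrations) == length(densities),
            length(concentrations) >= 5L, all(concentrations >= 0),
            all(densities >= 0))
  w <- if (is.null(sd)) rep(1, length(densities)) else {
    stopifnot(length(sd) == length(densities), all(sd > 0))
    1 / sd^2
  }
  c_ <- concentrations; d_ <- densities
  kd0 <- stats::approx(d_, c_, xout = max(d_) / 2, ties = mean)$y
  if (!is.finite(kd0)) kd0 <- stats::median(c_[c_ > 0])
  if (is.null(fix_n_H)) {
    fit <- minpack.lm::nlsLM(
      d_ ~ Bmax * c_^n_H / (Kd^n_H + c_^n_H),
      start = list(Bmax = max(d_) * 1.2, Kd = kd0, n_H = 1.5),
      weights = w,
      lower = c(Bmax = 1e-12, Kd = 1e-12, n_H = 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 500))
  } else {
    n_H <- fix_n_H
    fit <- minpack.lm::nlsLM(
      d_ ~ Bmax * c_^n_H / (Kd^n_H + c_^n_H),
      start = list(Bmax = max(d_) * 1.2, Kd = kd0),
      weights = w,
      lower = c(Bmax = 1e-12, Kd = 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 500))
  }
  co <- coef(fit)
  if (!is.null(fix_n_H)) co <- c(co, n_H = fix_n_H)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    rep(NA_real_, length(coef(fit))))
  if (!is.null(fix_n_H)) se <- c(se, NA_real_)
  extrapolated <- max(d_) < 0.7 * co[["Bmax"]]
  if (extrapolated)
    warning("titration does not reach 70% of fitted Bmax: ",
            "saturation is extrapolated")
  out <- list(Bmax = co[["Bmax"]], Kd = co[["Kd"]], n_H = co[["n_H"]],
              se = setNames(se[seq_len(3)], c("Bmax", "Kd", "n_H")),
              extrapolated = extrapolated,
              residuals = d_ - predict(fit),
              data = data.frame(conc_nM = c_, density = d_),
              fit = fit)
  class(out) <- "hill_fit"
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "Hill isotherm fit: Bmax = %.4g /um^2, Kd = %.4g nM, n_H = %.3g\n",
    x$Bmax, x$Kd, x$n_H))
  if (all(is.finite(x$se)))
    cat(sprintf("  SE: Bmax %.3g, Kd %.3g, n_H %.3g\n",
                x$se[1], x$se[2], x$se[3]))
  if (x$extrapolated) cat("  [saturation extrapolated]\n")
  invisible(x)
}

#' @export
plot.hill_fit <- function(x, ...) {
  graphics::plot(x$data$conc_nM, x$data$density, log = "x",
                 xlab = "concentration (nM)",
                 ylab = "surface density (/um^2)", pch = 16, ...)
  cc <- exp(seq(log(min(x$data$conc_nM[x$data$conc_nM > 0])),
                log(max(x$data$conc_nM)), length.out = 200))
  graphics::lines(cc, x$Bmax * cc^x$n_H / (x$Kd^x$n_H + cc^x$n_H),
                  col = 2, lwd = 2)
  invisible(x)
}
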