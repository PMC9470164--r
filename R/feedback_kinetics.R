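#' Normalize a sensor trace to the reaction coordinate x(t)
#'
#' Maps raw sensor intensity (or product density) to the reaction
#' coordinate `x = (I - I_start) / (I_end - I_start)`, clipped to
#' `[0, 1]`, where `I_start` is the first value and `I_end` the plateau
#' level (mean of the final `plateau_frac` of points).  A warning is
#' raised when the trace has not plateaued (final points vary by more
#' than `plateau_tol` of the full range).
#'
#' @param t time stamps, seconds.
#' @param intensity sensor intensity or product density.
#' @param plateau_frac fraction of trailing points defining the plateau.
#' @param plateau_tol allowed relative variation over the plateau.
#' @return Numeric vector `x(t)` in `[0, 1]`.
#' @export
normalize_reaction_coordinate <- function(t, intensity, plateau_frac = 0.1,
                                          plateau_tol = 0.02) {
  stopifnot(length(t) == length(intensity), length(t) >= 5L)
  n <- length(intensity)
  tail_idx <- seq.int(ceiling(n * (1 - plateau_frac)), n)
  i_start <- intensity[1L]
  i_end <- mean(intensity[tail_idx])
  plateaued <- diff(range(intensity[tail_idx])) <=
    plateau_tol * abs(i_end - i_start)
  if (!plateaued) {
    warning("trace has not plateaued: end anchor is uncertain")
    # without a plateau the tail mean understates the end level; fall
    # back to the final sample
    i_end <- intensity[n]
  }
  rng <- i_end - i_start
  if (rng == 0) stop("trace has zero dynamic range")
  pmin(pmax((intensity - i_start) / rng, 0), 1)
}

#' Local rate by windowed linear regression
#'
#' The derivative at each time point is the slope of a least-squares
#' line over the points within `halfwidth` seconds (the +/- 2 s window
#' of kinetic TIRF acquisitions by default).  End points where the
#' window is one-sided are still computed but flagged in the `one_sided`
#' attribute.
#'
#' @param t time stamps, seconds (uniformly sampled).
#' @param y series to differentiate.
#' @param halfwidth window half-width, seconds.
#' @return Numeric derivative series with logical attribute `one_sided`.
#' @export
local_rate <- function(t, y, halfwidth = 2) {
  stopifnot(length(t) == length(y), length(t) >= 3L, halfwidth > 0)
  n <- length(t)
  slope <- numeric(n)
  for (i in seq_len(n)) {
    sel <- which(abs(t - t[i]) <= halfwidth + 1e-9)
    if (length(sel) < 2L) sel <- max(1L, i - 1L):min(n, i + 1L)
    ts <- t[sel]; ys <- y[sel]
    slope[i] <- sum((ts - mean(ts)) * (ys - mean(ys))) / sum((ts - mean(ts))^2)
  }
  # windows truncated by the ends of the series are asymmetric
  one_sided <- t - halfwidth < t[1L] - 1e-9 | t + halfwidth > t[n] + 1e-9
  attr(slope, "one_sided") <- one_sided
  slope
}

#' Per-enzyme catalytic velocity along a reaction trace
#'
#' The effective phosphorylation rate per membrane-bound enzyme,
#' `v_molecule(t) = dP/dt * 1/E(t)`, paired with the remaining substrate
#' density `S(t) = S0 - P(t)`; `dP/dt` is the [local_rate()] windowed
#' regression slope.  Points where the enzyme density is below `e_floor`
#' are masked (`NA`) rather than divided.
#'
#' @param t time stamps, seconds.
#' @param P product surface density, lipids/um^2.
#' @param E enzyme surface density time series, molecules/um^2.
#' @param S0 initial substrate density, lipids/um^2.
#' @param e_floor minimum enzyme density for a valid quotient.
#' @param halfwidth derivative window half-width, seconds.
#' @return Data frame `t`, `S`, `v` (lipids/um^2/s per enzyme; `NA`
#'   where masked), `masked`.
#' @export
per_enzyme_velocity <- function(t, P, E, S0, e_floor = 0.05, halfwidth = 2) {
  stopifnot(length(t) == length(P), length(E) %in% c(1L, length(P)),
            S0 > 0)
  if (length(E) == 1L) E <- rep(E, length(P))
  dPdt <- local_rate(t, P, halfwidth)
  masked <- !is.finite(E) | E < e_floor
  v <- ifelse(masked, NA_real_, dPdt / E)
  data.frame(t = t, S = S0 - P, v = v, masked = masked)
}

#' Decompose positive feedback order from a reaction coordinate trace
#'
#' Fits the composition dynamics `dx/dt = (k0 + k1 x [+ k2 x^2])(1 - x)`.
#' The feedback profile is built by regressing the [local_rate()]
#' derivative on the basis `(1-x)`, `x(1-x)`, `x^2(1-x)` over `x` in
#' `(xmin, xmax)` where the `(1 - x)` factor does not amplify noise.
#' With `model_order = "auto"` the quadratic term is kept only when an
#' F-test against the first-order model is significant at `f_alpha` and
#' the fitted `k2` is kinetically material (`k2_min_frac`); a
#' second-order requirement is the signature of membrane-mediated
#' dimerization, while first-order feedback corresponds to simple
#' product binding.
#'
#' Numerically differentiating a noisy trace is inefficient, so by
#' default (`refine = TRUE`) the coefficients of the selected order are
#' then refined by trajectory least squares: the rate law is integrated
#' and `sum((x_model - x_obs)^2)` minimized over the coefficients (and
#' the initial composition), starting from the derivative-based
#' estimates.  Order selection always uses the derivative-space F-test.
#'
#' @param t time stamps, seconds.
#' @param x reaction coordinate trace in `[0, 1]`.
#' @param model_order `"auto"`, `1` or `2`.
#' @param xmin,xmax fitting domain on the reaction coordinate.
#' @param f_alpha significance level of the order-selection F-test.
#' @param k2_min_frac practical-significance guard for auto selection:
#'   the quadratic term is kept only when `|k2|` exceeds this fraction
#'   of the total rate amplitude `|k0| + |k1| + |k2|` (a statistically
#'   detectable but kinetically negligible curvature stays first order).
#' @param halfwidth derivative window half-width, seconds.
#' @param refine logical; refine coefficients by trajectory least
#'   squares (default `TRUE`).
#' @return Object of class `feedback_fit`: `k0`, `k1`, `k2`, `order`,
#'   `rss` (derivative space), `traj_rss` (trajectory space, if
#'   refined), `f_p`, `unphysical` flag (negative fitted `k(x)` on
#'   `[0, 1]`).
#' @export
fit_feedback <- function(t, x, model_order = c("auto", "1", "2"),
                         xmin = 0.02, xmax = 0.98, f_alpha = 0.01,
                         k2_min_frac = 0.02, halfwidth = 2,
                         refine = TRUE) {
  model_order <- match.arg(as.character(model_order[1]),
                           c("auto", "1", "2"))
  stopifnot(length(t) == length(x))
  if (min(x) > 0.1 || max(x) < 0.9)
    stop("reaction coordinate must span at least [0.1, 0.9] to resolve ",
         "the feedback order")
  dxdt <- local_rate(t, x, halfwidth)
  sel <- x > xmin & x < xmax & is.finite(dxdt)
  xs <- x[sel]; ys <- dxdt[sel]
  b0 <- (1 - xs); b1 <- xs * (1 - xs); b2 <- xs^2 * (1 - xs)

  fit1 <- lm(ys ~ 0 + b0 + b1)
  fit2 <- lm(ys ~ 0 + b0 + b1 + b2)
  rss1 <- sum(residuals(fit1)^2)
  rss2 <- sum(residuals(fit2)^2)
  df2 <- length(ys) - 3L
  f_stat <- (rss1 - rss2) / (rss2 / df2)
  f_p <- pf(f_stat, 1, df2, lower.tail = FALSE)

  k2_hat <- unname(coef(fit2)[3])
  k2_material <- abs(k2_hat) >
    k2_min_frac * sum(abs(coef(fit2)))
  order <- switch(model_order,
                  "1" = 1L, "2" = 2L,
                  auto = if (is.finite(f_p) && f_p < f_alpha && k2_material)
                    2L else 1L)
  if (order == 1L) {
    k <- c(unname(coef(fit1)), 0)
    rss <- rss1
  } else {
    k <- unname(coef(fit2))
    rss <- rss2
  }

  traj_rss <- NA_real_
  if (refine) {
    integrate_k <- function(kc, x_init) {
      rhs <- function(tt, y, p)
        list(max(kc[1] + kc[2] * y[1] + kc[3] * y[1]^2, 0) * (1 - y[1]))
      sol <- deSolve::ode(y = c(x = min(max(x_init, 0), 1)), times = t,
                          func = rhs, parms = NULL, method = "lsoda")
      sol[, "x"]
    }
    free <- if (order == 1L) 1:2 else 1:3
    obj <- function(par) {
      kc <- c(0, 0, 0)
      kc[free] <- par[seq_along(free)]
      sum((integrate_k(kc, par[length(par)]) - x)^2)
    }
    start <- c(pmax(k[free], 1e-8), min(max(x[1], 1e-4), 0.45))
    opt <- tryCatch(stats::nlminb(start, obj,
                                  lower = rep(0, length(start)),
                                  upper = c(rep(Inf, length(free)), 0.5),
                                  control = list(iter.max = 500)),
                    error = function(e) NULL)
    if (!is.null(opt)) opt$value <- opt$objective
    if (!is.null(opt) && opt$value < sum((integrate_k(k, x[1]) - x)^2)) {
      k[free] <- opt$par[seq_along(free)]
      traj_rss <- opt$value
    }
  }

  kx <- function(z) k[1] + k[2] * z + k[3] * z^2
  grid <- seq(0, 1, length.out = 201)
  unphysical <- any(kx(grid) < 0)
  if (unphysical)
    warning("fitted k(x) is negative somewhere on [0, 1]")
  out <- list(k0 = k[1], k1 = k[2], k2 = k[3], order = order,
              rss = rss, traj_rss = traj_rss, f_p = f_p,
              unphysical = unphysical, n_points = length(ys))
  class(out) <- "feedback_fit"
  out
}

#' @export
print.feedback_fit <- function(x, ...) {
  cat(sprintf("Feedback fit (order %d, %d points): dx/dt = k(x)(1-x)\n",
              x$order, x$n_points))
  cat(sprintf("  k(x) = %.4g + %.4g x%s\n", x$k0, x$k1,
              if (x$order == 2L) sprintf(" + %.4g x^2", x$k2) else ""))
  if (x$unphysical) cat("  [flagged: k(x) < 0 somewhere on [0,1]]\n")
  invisible(x)
}

#' Reaction half-time
#'
#' Time of the first crossing of `x = 0.5`, by linear interpolation
#' between the bracketing samples.
#'
#' @param t time stamps, seconds.
#' @param x normalized reaction coordinate.
#' @return Half-time in seconds (`NA` if the trace never crosses 0.5).
#' @export
half_time <- function(t, x) {
  stopifnot(length(t) == length(x))
  above <- x >= 0.5
  if (above[1L]) return(t[1L])
  i <- which(above)[1L]
  if (is.na(i)) return(NA_real_)
  t[i - 1L] + (0.5 - x[i - 1L]) / (x[i] - x[i - 1L]) * (t[i] - t[i - 1L])
}
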