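#' Kinase-phosphatase competition model for one membrane corral
#'
#' Defines the composition dynamics of the bistable competitive reaction
#' `dx/dt = g(x) = (k0 + k1 x + k2 x^2)(1 - x) - (p0 + p1 (1 - x)) x`,
#' where x is the PI(4,5)P2 fraction of the PIP lipid pool, the kinase
#' carries polynomial positive feedback in product (second order for the
#' dimerizing wild type, first order for a dimerization-deficient
#' mutant) and the opposing 5-phosphatase carries first-order feedback
#' in its own product `1 - x`.  In stochastic simulations the corral
#' holds `round(S_total * corral_area)` discrete lipids, and kinase
#' copies arrive from solution and depart with the stated rates; an
#' optional `recruit_coupling` c multiplies the arrival rate by
#' `(1 + c x)` to represent product-enhanced recruitment (off by
#' default; the composition feedback then lives entirely in `k(x)`).
#'
#' @param k_coeffs kinase coefficients `c(k0, k1, k2)`, 1/s.
#' @param phosphatase_coeffs phosphatase coefficients `c(p0, p1)`, 1/s.
#' @param corral_area corral area, um^2 (5 x 5 um corrals by default).
#' @param S_total total PIP lipid density, lipids/um^2.
#' @param kinase_kon kinase on-rate, 1/(nM s um^2).
#' @param kinase_solution_conc kinase concentration, nM.
#' @param kinase_dwell_tau mean kinase dwell, seconds.
#' @param recruit_coupling product-recruitment coupling c (>= 0).
#' @return Object of class `competition_model`.
#' @export
competition_model <- function(k_coeffs, phosphatase_coeffs,
                              corral_area = 25, S_total = 55555.6,
                              kinase_kon = 0.1,
                              kinase_solution_conc = 50,
                              kinase_dwell_tau = 2,
                              recruit_coupling = 0) {
  stopifnot(length(k_coeffs) == 3L, length(phosphatase_coeffs) == 2L,
            all(k_coeffs >= 0), all(phosphatase_coeffs >= 0),
            corral_area > 0, S_total > 0, kinase_kon >= 0,
            kinase_solution_conc >= 0, kinase_dwell_tau > 0,
            recruit_coupling >= 0)
  m <- list(k = as.numeric(k_coeffs), p = as.numeric(phosphatase_coeffs),
            corral_area = corral_area, S_total = S_total,
            lipid_count = as.integer(round(S_total * corral_area)),
            kinase_kon = kinase_kon,
            kinase_solution_conc = kinase_solution_conc,
            kinase_dwell_tau = kinase_dwell_tau,
            recruit_coupling = recruit_coupling)
  class(m) <- "competition_model"
  m
}

#' @export
print.competition_model <- function(x, ...) {
  cat("Kinase-phosphatase competition model\n")
  cat(sprintf("  k(x) = %.4g + %.4g x + %.4g x^2;  phosphatase (%.4g + %.4g(1-x)) x\n",
              x$k[1], x$k[2], x$k[3], x$p[1], x$p[2]))
  cat(sprintf("  corral %.3g um^2, %d lipids\n", x$corral_area, x$lipid_count))
  invisible(x)
}

# internal: net rate g(x) and its polynomial coefficients (degree <= 3)
.g_poly <- function(model) {
  k <- model$k; p <- model$p
  c(k[1],
    k[2] - k[1] - p[1] - p[2],
    k[3] - k[2] + p[2],
    -k[3])
}

.g_eval <- function(model, x) {
  co <- .g_poly(model)
  co[1] + co[2] * x + co[3] * x^2 + co[4] * x^3
}

#' Steady states of the competition model
#'
#' All real roots of `g(x) = 0` on `[0, 1]` with their stability from
#' the sign of `g'(x)`.  The right-hand side is a polynomial of degree
#' at most 3, so root finding is exhaustive ([base::polyroot()]).  A
#' degenerate model with `g` identically zero (a continuum of steady
#' states) is flagged via the `degenerate` attribute.
#'
#' @param model a [competition_model()].
#' @param tol root and de-duplication tolerance.
#' @return Data frame `x`, `stable` (logical), sorted by `x`, with
#'   attribute `degenerate`.
#' @export
find_steady_states <- function(model, tol = 1e-9) {
  stopifnot(inherits(model, "competition_model"))
  co <- .g_poly(model)
  if (all(abs(co) < tol)) {
    out <- data.frame(x = numeric(), stable = logical())
    attr(out, "degenerate") <- TRUE
    warning("g(x) is identically zero: continuum of (marginal) steady states")
    return(out)
  }
  deg <- max(which(abs(co) >= tol)) - 1L
  roots <- if (deg == 0L) complex(0) else polyroot(co[seq_len(deg + 1L)])
  x <- Re(roots[abs(Im(roots)) < 1e-7])
  x <- x[x >= -tol & x <= 1 + tol]
  x <- pmin(pmax(x, 0), 1)
  x <- sort(unique(round(x / tol) * tol))
  # drop near-duplicates
  if (length(x) > 1L) x <- x[c(TRUE, diff(x) > 1e-6)]
  # stability from the slope of g (central difference)
  h <- 1e-6
  gp <- (.g_eval(model, pmin(x + h, 1)) - .g_eval(model, pmax(x - h, 0))) /
    (pmin(x + h, 1) - pmax(x - h, 0))
  out <- data.frame(x = x, stable = gp < 0)
  attr(out, "degenerate") <- FALSE
  out
}

#' Parameter range of deterministic bistability
#'
#' Sweeps one scalar model parameter and returns the interval over which
#' [find_steady_states()] reports at least two stable states.  Edges of
#' the interval are refined by bisection between bracketing grid points
#' (they correspond to saddle-node bifurcations where two roots merge).
#'
#' @param model a [competition_model()].
#' @param param which coefficient to sweep: `"p0"`, `"p1"`, `"k0"`,
#'   `"k1"` or `"k2"`.
#' @param lower,upper sweep bounds.
#' @param n_grid grid resolution of the initial scan.
#' @param bisect_iter bisection refinement iterations per edge.
#' @return Numeric `c(lo, hi)` of the (largest) bistable interval, or a
#'   zero-length numeric vector if no bistability is found; attribute
#'   `grid` holds the scan (`value`, `n_stable`).
#' @export
bistable_range <- function(model, param = "p0", lower = 0, upper = 1,
                           n_grid = 200L, bisect_iter = 40L) {
  stopifnot(inherits(model, "competition_model"),
            param %in% c("p0", "p1", "k0", "k1", "k2"), upper > lower)
  set_par <- function(m, v) {
    switch(param,
           p0 = { m$p[1] <- v; m }, p1 = { m$p[2] <- v; m },
           k0 = { m$k[1] <- v; m }, k1 = { m$k[2] <- v; m },
           k2 = { m$k[3] <- v; m })
  }
  n_stable <- function(v) {
    ss <- suppressWarnings(find_steady_states(set_par(model, v)))
    sum(ss$stable)
  }
  grid <- seq(lower, upper, length.out = n_grid)
  ns <- vapply(grid, n_stable, numeric(1))
  bist <- ns >= 2
  scan <- data.frame(value = grid, n_stable = ns)
  if (!any(bist)) {
    out <- numeric(0)
    attr(out, "grid") <- scan
    return(out)
  }
  # largest contiguous bistable run
  r <- rle(bist)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  widest <- runs[which.max(r$lengths[runs])]
  i0 <- starts[widest]; i1 <- ends[widest]
  # bisect the two edges
  refine <- function(in_idx, out_idx) {
    a <- grid[in_idx]; b <- grid[out_idx]
    for (i in seq_len(bisect_iter)) {
      m <- (a + b) / 2
      if (n_stable(m) >= 2) a <- m else b <- m
    }
    (a + b) / 2
  }
  lo <- if (i0 > 1L) refine(i0, i0 - 1L) else grid[i0]
  hi <- if (i1 < n_grid) refine(i1, i1 + 1L) else grid[i1]
  out <- c(lo, hi)
  attr(out, "grid") <- scan
  out
}

#' Stochastic ensemble of corral reactions
#'
#' Runs `n_corrals` independent exact stochastic simulations of the
#' competition model (per-corral RNG streams derived from `seed`), with
#' open boundaries to solution for the kinase but no lipid exchange.
#' Summaries follow the corral-array experiment: the fraction of corrals
#' ending PI(4,5)P2-dominated (`x > 0.5` at `t_end`), per-corral half
#' and completion times, and their coefficients of variation.
#'
#' @param model a [competition_model()].
#' @param n_corrals number of corrals (>= 1).
#' @param seed integer root seed.
#' @param t_end simulated time, seconds (default 1800 s).
#' @param x0 initial composition.
#' @param dt_record recording interval, seconds.
#' @param completion_x coordinate defining "completion" (default 0.9).
#' @return Object of class `corral_ensemble`: `trajectories` (long data
#'   frame `corral_id`, `t`, `x`, `n_kinase`), `fraction_product` (share
#'   of corrals with final x > 0.5), `half_times`, `completion_times`,
#'   `cv_half`, `cv_completion`, `incomplete` flag.
#' @export
run_corral_ensemble <- function(model, n_corrals, seed = 1L, t_end = 1800,
                                x0 = 0.5, dt_record = 2,
                                completion_x = 0.9) {
  stopifnot(inherits(model, "competition_model"), n_corrals >= 1)
  n_lipid <- model$lipid_count
  if (n_lipid < 100)
    stop("corral too small: need >= 100 lipids (S_total * corral_area)")
  arr <- model$kinase_kon * model$kinase_solution_conc * model$corral_area
  e_mean <- arr * model$kinase_dwell_tau
  times <- seq(0, t_end, by = dt_record)
  traj <- vector("list", n_corrals)
  for (i in seq_len(n_corrals)) {
    set.seed(stream_seed(seed, "corral", i))
    sim <- corral_gillespie_cpp(
      n_lipid = n_lipid, n_p0 = as.integer(round(x0 * n_lipid)),
      k = model$k, p = model$p,
      arrival_rate = arr, departure_rate = 1 / model$kinase_dwell_tau,
      e_mean = e_mean, recruit_coupling = model$recruit_coupling,
      t_end = t_end, dt_record = dt_record)
    traj[[i]] <- data.frame(corral_id = i, t = times, x = sim$x,
                            n_kinase = sim$n_kinase)
  }
  trajectories <- do.call(rbind, traj)
  final_x <- vapply(traj, function(d) d$x[nrow(d)], numeric(1))
  half_times <- vapply(traj, function(d) half_time(d$t, d$x), numeric(1))
  completion_times <- vapply(traj, function(d) {
    i <- which(d$x >= completion_x)[1L]
    if (is.na(i)) NA_real_ else d$t[i]
  }, numeric(1))
  cv <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2L || mean(v) == 0) NA_real_ else sd(v) / mean(v)
  }
  out <- list(trajectories = trajectories,
              fraction_product = mean(final_x > 0.5),
              final_x = final_x,
              half_times = half_times,
              completion_times = completion_times,
              cv_half = cv(half_times),
              cv_completion = cv(completion_times),
              incomplete = all(is.na(completion_times)) &&
                all(final_x < completion_x),
              model = model, t_end = t_end, n_corrals = n_corrals)
  if (out$incomplete)
    warning("no corral reached the completion threshold by t_end")
  class(out) <- "corral_ensemble"
  out
}

#' @export
print.corral_ensemble <- function(x, ...) {
  cat(sprintf("Corral ensemble: %d corrals, t_end = %.4g s\n",
              x$n_corrals, x$t_end))
  cat(sprintf("  fraction ending PI(4,5)P2-dominated: %.3f\n",
              x$fraction_product))
  if (is.finite(x$cv_completion))
    cat(sprintf("  completion time CV: %.3f\n", x$cv_completion))
  invisible(x)
}

#' Outcome fraction versus corral size (stochastic geometry sensing)
#'
#' For a model parameterized near (typically just outside) the
#' deterministic bistable range, runs stochastic ensembles at a series
#' of corral areas and reports the fraction of corrals ending
#' PI(4,5)P2-dominated per area, with binomial 95% confidence intervals.
#' Small corrals feel copy-number fluctuations strongly, so the outcome
#' depends on system size.
#'
#' @param model a [competition_model()] (its `corral_area` is replaced
#'   by each element of `areas`).
#' @param areas strictly increasing corral areas, um^2.
#' @param n_corrals corrals per area.
#' @param seed integer root seed.
#' @param t_end simulated time per corral, seconds.
#' @param x0 initial composition.
#' @param dt_record recording interval, seconds.
#' @return Data frame `area`, `fraction_product`, `ci_lo`, `ci_hi`, `n`.
#' @export
geometry_sensing_scan <- function(model, areas, n_corrals = 100L, seed = 1L,
                                  t_end = 1800, x0 = 0.5, dt_record = 2) {
  stopifnot(inherits(model, "competition_model"),
            length(areas) >= 1L, all(diff(areas) > 0))
  res <- lapply(seq_along(areas), function(i) {
    m <- model
    m$corral_area <- areas[i]
    m$lipid_count <- as.integer(round(model$S_total * areas[i]))
    # phosphatase-dominated corrals legitimately never complete; the
    # per-ensemble completeness warning is noise in a scan
    ens <- suppressWarnings(
      run_corral_ensemble(m, n_corrals,
                          seed = stream_seed(seed, "area", i),
                          t_end = t_end, x0 = x0, dt_record = dt_record))
    k <- sum(ens$final_x > 0.5)
    ci <- stats::binom.test(k, n_corrals)$conf.int
    data.frame(area = areas[i], fraction_product = k / n_corrals,
               ci_lo = ci[1], ci_hi = ci[2], n = n_corrals)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
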