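#' Fit exponential(-mixture) models to a dwell-time sample
#'
#' Builds the empirical survival curve 1 - CDF binned at the frame
#' interval, and fits `f(t) = exp(-t/tau)` in log10-survival space.  The
#' fit escalates to the two-component model
#' `alpha*exp(-t/tau1) + (1-alpha)*exp(-t/tau2)` only when the
#' single-exponential fit is of low quality: its coefficient of
#' determination in log-survival space (over the first three decades)
#' falls below `r2_threshold` *and* an F-test against the two-component
#' model is significant at `f_alpha`.  Dwells shorter than one frame are
#' unobservable, so the survival curve is fit from the second bin onward.
#'
#' Convention: components are ordered `tau1 <= tau2` and `alpha` is the
#' fraction of the fast-dissociating component (`tau1`).
#'
#' @param dwells numeric vector of dwell times, seconds (>= 50 values).
#' @param frame_interval frame interval (= survival bin width), seconds.
#' @param max_components 1 or 2.
#' @param r2_threshold single-model quality gate (default 0.99).
#' @param f_alpha significance level of the escalation F-test.
#' @return Object of class `dwell_fit`: fields `n_components`, `tau1`,
#'   `tau2`, `alpha`, `n_molecules`, `r2`, `rss`, `f_p`, and the binned
#'   survival curve in `$survival`.
#' @seealso [correct_bleaching()], [fit_dwell_mle()]
#' @export
fit_dwell <- function(dwells, frame_interval, max_components = 2L,
                      r2_threshold = 0.99, f_alpha = 0.01) {
  .check_pos(frame_interval, "frame_interval")
  dwells <- dwells[is.finite(dwells)]
  if (length(dwells) < 50L)
    stop("need >= 50 dwell times to fit a survival model (got ",
         length(dwells), ")")
  stopifnot(max_components %in% 1:2)

  dt <- frame_interval
  eps <- dt * 1e-6
  kmax <- max(2L, ceiling(max(dwells) / dt))
  tk <- seq_len(kmax) * dt
  surv <- vapply(tk, function(ti) mean(dwells > ti + eps), numeric(1))
  # Fit from the start of the decay: dwells shorter than one frame are
  # unobservable (first-bin truncation), and a minimum-duration track
  # filter leaves leading bins at survival 1.  Renormalizing the curve
  # at the last full bin is exact for exponentials (memorylessness) and
  # keeps the amplitude-free models unbiased for conditioned samples.
  k_start <- max(2L, which(surv < 1)[1L])
  t0 <- (k_start - 1L) * dt
  ref <- if (k_start > 1L) surv[k_start - 1L] else 1
  keep <- surv > 0 & surv >= max(surv) * 1e-3
  keep[seq_len(k_start - 1L)] <- FALSE
  tt <- tk[keep] - t0
  y <- log10(surv[keep] / ref)
  if (length(tt) < 4L)
    stop("too few populated survival bins to fit (", length(tt), ")")

  # single exponential: log10 S = -t / (tau * ln 10); exact LS through origin
  slope <- sum(tt * y) / sum(tt^2)
  tau_s <- -1 / (slope * log(10))
  if (!is.finite(tau_s) || tau_s <= 0)
    stop("survival curve is not decaying; cannot fit a dwell time")
  res1 <- y - (-tt / (tau_s * log(10)))
  rss1 <- sum(res1^2)
  tss <- sum((y - mean(y))^2)
  r2_1 <- 1 - rss1 / tss

  fit2 <- NULL
  if (max_components == 2L) {
    mhat <- mean(dwells)
    starts <- expand.grid(alpha = c(0.2, 0.5, 0.8),
                          tau1 = mhat * c(0.3, 0.6),
                          tau2 = mhat * c(1.5, 4))
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      f <- tryCatch(minpack.lm::nlsLM(
        y ~ log10(alpha * exp(-tt / tau1) + (1 - alpha) * exp(-tt / tau2)),
        start = as.list(starts[i, ]),
        lower = c(alpha = 0, tau1 = dt / 10, tau2 = dt / 10),
        upper = c(alpha = 1, tau1 = Inf, tau2 = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(f)) {
        rss <- sum(residuals(f)^2)
        if (is.null(best) || rss < best$rss) best <- list(fit = f, rss = rss)
      }
    }
    fit2 <- best
  }

  f_p <- NA_real_
  use2 <- FALSE
  if (!is.null(fit2)) {
    n_pts <- length(tt)
    df2 <- n_pts - 3L
    f_stat <- ((rss1 - fit2$rss) / 2) / (fit2$rss / df2)
    f_p <- pf(f_stat, 2, df2, lower.tail = FALSE)
    use2 <- (r2_1 < r2_threshold) && is.finite(f_p) && (f_p < f_alpha)
  }

  if (use2) {
    co <- coef(fit2$fit)
    tau1 <- co[["tau1"]]; tau2 <- co[["tau2"]]; alpha <- co[["alpha"]]
    if (tau1 > tau2) { tmp <- tau1; tau1 <- tau2; tau2 <- tmp; alpha <- 1 - alpha }
    degenerate <- abs(tau2 - tau1) / tau2 < 0.1 || alpha < 0.01 || alpha > 0.99
    if (!degenerate) {
      yhat <- log10(alpha * exp(-tt / tau1) + (1 - alpha) * exp(-tt / tau2))
      out <- list(n_components = 2L, tau1 = tau1, tau2 = tau2, alpha = alpha,
                  n_molecules = length(dwells), r2 = 1 - fit2$rss / tss,
                  rss = fit2$rss, f_p = f_p,
                  survival = data.frame(t = tt + t0, surv = surv[keep],
                                        fitted = ref * 10^yhat),
                  frame_interval = dt, tau_corrected = NULL)
      class(out) <- "dwell_fit"
      return(out)
    }
  }
  out <- list(n_components = 1L, tau1 = tau_s, tau2 = NA_real_,
              alpha = 1, n_molecules = length(dwells), r2 = r2_1,
              rss = rss1, f_p = f_p,
              survival = data.frame(t = tt + t0, surv = surv[keep],
                                    fitted = ref * exp(-tt / tau_s)),
              frame_interval = dt, tau_corrected = NULL)
  class(out) <- "dwell_fit"
  out
}

#' @export
print.dwell_fit <- function(x, ...) {
  cat(sprintf("Dwell-time fit (%d component%s, N = %d)\n", x$n_components,
              if (x$n_components > 1) "s" else "", x$n_molecules))
  if (x$n_components == 1L) {
    cat(sprintf("  tau = %.4g s   (R2 = %.4f in log-survival space)\n",
                x$tau1, x$r2))
  } else {
    cat(sprintf("  tau1 = %.4g s, tau2 = %.4g s, alpha(fast) = %.3f (R2 = %.4f)\n",
                x$tau1, x$tau2, x$alpha, x$r2))
  }
  if (!is.null(x$tau_corrected))
    cat(sprintf("  bleach-corrected tau: %s s\n",
                paste(signif(x$tau_corrected, 4), collapse = ", ")))
  invisible(x)
}

#' @export
plot.dwell_fit <- function(x, ...) {
  graphics::plot(x$survival$t, log10(x$survival$surv),
                 xlab = "dwell time (s)", ylab = "log10(1 - CDF)",
                 pch = 16, cex = 0.6, ...)
  graphics::lines(x$survival$t, log10(x$survival$fitted), col = 2, lwd = 2)
  invisible(x)
}

#' Maximum-likelihood exponential-mixture fit (EM)
#'
#' Independent cross-check for [fit_dwell()]: fits a 1- or 2-component
#' exponential mixture to the raw (unbinned) dwell sample by
#' expectation-maximization, with the same component-ordering convention.
#'
#' @param dwells numeric vector of dwell times, seconds.
#' @param n_components 1 or 2.
#' @param max_iter,tol EM iteration controls.
#' @return List with `tau1`, `tau2`, `alpha`, `loglik`, `n_iter`.
#' @export
fit_dwell_mle <- function(dwells, n_components = 2L, max_iter = 1000L,
                          tol = 1e-10) {
  dwells <- dwells[is.finite(dwells) & dwells > 0]
  if (n_components == 1L) {
    tau <- mean(dwells)
    return(list(tau1 = tau, tau2 = NA_real_, alpha = 1,
                loglik = sum(stats::dexp(dwells, 1 / tau, log = TRUE)),
                n_iter = 0L))
  }
  m <- mean(dwells)
  tau <- c(0.5, 2) * m
  alpha <- 0.5
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- alpha * stats::dexp(dwells, 1 / tau[1])
    d2 <- (1 - alpha) * stats::dexp(dwells, 1 / tau[2])
    w <- d1 / (d1 + d2)
    alpha <- mean(w)
    tau[1] <- sum(w * dwells) / sum(w)
    tau[2] <- sum((1 - w) * dwells) / sum(1 - w)
    ll <- sum(log(d1 + d2))
    if (is.finite(ll) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  if (tau[1] > tau[2]) { tau <- rev(tau); alpha <- 1 - alpha }
  list(tau1 = tau[1], tau2 = tau[2], alpha = alpha, loglik = ll, n_iter = it)
}

#' Correct observed dwell times for photobleaching
#'
#' Unbinding and photobleaching are competing exponential processes, so
#' the observed rate is the sum of the true unbinding rate and the
#' bleaching rate: `1/tau_obs = 1/tau_true + 1/tau_bleach`, giving
#' `tau_true = 1 / (1/tau_obs - 1/tau_bleach)`.
#'
#' @param fit a [fit_dwell()] result, or a numeric vector of observed
#'   dwell time constants (seconds).
#' @param tau_bleach photobleaching time constant, seconds.
#' @return For a `dwell_fit` input, the same object with a
#'   `tau_corrected` field (one value per component); for numeric input,
#'   the corrected values.
#' @export
correct_bleaching <- function(fit, tau_bleach) {
  .check_pos(tau_bleach, "tau_bleach", allow_inf = TRUE)
  corr <- function(tau) {
    if (any(tau >= tau_bleach))
      stop("observed tau >= tau_bleach: unbinding slower than bleaching ",
           "cannot be resolved")
    1 / (1 / tau - 1 / tau_bleach)
  }
  if (inherits(fit, "dwell_fit")) {
    taus <- c(fit$tau1, if (fit$n_components == 2L) fit$tau2)
    fit$tau_corrected <- corr(taus)
    fit$tau_bleach <- tau_bleach
    return(fit)
  }
  corr(fit)
}

#' Fit Brownian step-size (mixture) models to a displacement sample
#'
#' Builds the probability-density histogram of per-frame 2D displacements
#' (bin width 0.01 um; density = frequency / bin width) and least-squares
#' fits the one-species density
#' `f(r) = r / (2 D tau) * exp(-r^2 / (4 D tau))`,
#' escalating to the two-species mixture
#' `alpha f(r; D1) + (1 - alpha) f(r; D2)` under the same quality
#' criterion as [fit_dwell()] (single-fit R^2 below `r2_threshold` and
#' F-test significant).  Fitting uses trust-region least squares with
#' multiple starting values of `alpha` to avoid local minima; ties are
#' broken by lowest residual, then fewest components.
#'
#' Convention: `D1 <= D2` and `alpha` is the fraction of the slow
#' component (`D1`).
#'
#' @param steps numeric vector of step sizes, um (>= 1000 values).
#' @param frame_interval time between steps, seconds.
#' @param bin_width histogram bin width, um.
#' @param max_components 1 or 2.
#' @param r2_threshold,f_alpha escalation criterion (see [fit_dwell()]).
#' @return Object of class `step_fit`: `n_components`, `D1`, `D2`,
#'   `alpha`, `frame_interval`, `n_steps`, `r2`, `rss`, histogram in
#'   `$density`, and `at_bound` flag.
#' @export
fit_steps <- function(steps, frame_interval, bin_width = 0.01,
                      max_components = 2L, r2_threshold = 0.99,
                      f_alpha = 0.01) {
  .check_pos(frame_interval, "frame_interval")
  .check_pos(bin_width, "bin_width")
  steps <- steps[is.finite(steps)]
  if (length(steps) < 1000L)
    stop("need >= 1000 steps to fit the displacement distribution (got ",
         length(steps), ")")
  if (all(steps == 0)) stop("all step sizes are zero")

  tau <- frame_interval
  breaks <- seq(0, max(steps) + bin_width, by = bin_width)
  h <- graphics::hist(steps, breaks = breaks, plot = FALSE)
  r <- h$mids
  dens <- h$counts / (length(steps) * bin_width)

  d_lower <- 1e-6
  ray <- function(r, D) r / (2 * D * tau) * exp(-r^2 / (4 * D * tau))
  mhat <- mean(steps^2) / (4 * tau)  # moment estimator as initialization

  f1 <- tryCatch(minpack.lm::nlsLM(dens ~ ray(r, D), start = list(D = mhat),
                                   lower = c(D = d_lower)),
                 error = function(e) NULL)
  if (is.null(f1)) stop("single-species step fit failed to converge")
  rss1 <- sum(residuals(f1)^2)
  tss <- sum((dens - mean(dens))^2)
  r2_1 <- 1 - rss1 / tss
  D_s <- coef(f1)[["D"]]

  best <- NULL
  if (max_components == 2L) {
    starts <- expand.grid(alpha = c(0.2, 0.5, 0.8),
                          s1 = c(0.2, 0.4), s2 = c(1.5, 3))
    for (i in seq_len(nrow(starts))) {
      st <- list(alpha = starts$alpha[i], D1 = mhat * starts$s1[i],
                 D2 = mhat * starts$s2[i])
      f <- tryCatch(minpack.lm::nlsLM(
        dens ~ alpha * ray(r, D1) + (1 - alpha) * ray(r, D2),
        start = st,
        lower = c(alpha = 0, D1 = d_lower, D2 = d_lower),
        upper = c(alpha = 1, D1 = Inf, D2 = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(f)) {
        rss <- sum(residuals(f)^2)
        if (is.null(best) || rss < best$rss) best <- list(fit = f, rss = rss)
      }
    }
  }

  f_p <- NA_real_
  use2 <- FALSE
  if (!is.null(best)) {
    df2 <- length(r) - 3L
    f_stat <- ((rss1 - best$rss) / 2) / (best$rss / df2)
    f_p <- pf(f_stat, 2, df2, lower.tail = FALSE)
    use2 <- (r2_1 < r2_threshold) && is.finite(f_p) && (f_p < f_alpha)
  }

  if (use2) {
    co <- coef(best$fit)
    D1 <- co[["D1"]]; D2 <- co[["D2"]]; alpha <- co[["alpha"]]
    if (D1 > D2) { tmp <- D1; D1 <- D2; D2 <- tmp; alpha <- 1 - alpha }
    degenerate <- abs(D2 - D1) / D2 < 0.1 || alpha < 0.01 || alpha > 0.99
    if (!degenerate) {
      fitted2 <- alpha * ray(r, D1) + (1 - alpha) * ray(r, D2)
      out <- list(n_components = 2L, D1 = D1, D2 = D2, alpha = alpha,
                  frame_interval = tau, n_steps = length(steps),
                  r2 = 1 - best$rss / tss, rss = best$rss, f_p = f_p,
                  density = data.frame(r = r, density = dens,
                                       fitted = fitted2),
                  at_bound = min(D1, D2) <= d_lower * 1.01)
      class(out) <- "step_fit"
      return(out)
    }
  }
  out <- list(n_components = 1L, D1 = D_s, D2 = NA_real_, alpha = 1,
              frame_interval = tau, n_steps = length(steps),
              r2 = r2_1, rss = rss1, f_p = f_p,
              density = data.frame(r = r, density = dens,
                                   fitted = ray(r, D_s)),
              at_bound = D_s <= d_lower * 1.01)
  class(out) <- "step_fit"
  if (out$at_bound) warning("fitted D at parameter bound")
  out
}

#' @export
print.step_fit <- function(x, ...) {
  cat(sprintf("Step-size fit (%d component%s, %d steps at %.3g s)\n",
              x$n_components, if (x$n_components > 1) "s" else "",
              x$n_steps, x$frame_interval))
  if (x$n_components == 1L) {
    cat(sprintf("  D = %.4g um^2/s   (R2 = %.4f)\n", x$D1, x$r2))
  } else {
    cat(sprintf("  D1 = %.4g, D2 = %.4g um^2/s, alpha(slow) = %.3f (R2 = %.4f)\n",
                x$D1, x$D2, x$alpha, x$r2))
  }
  invisible(x)
}

#' @export
plot.step_fit <- function(x, ...) {
  graphics::plot(x$density$r, x$density$density, type = "h", col = "grey60",
                 xlab = "step size (um)", ylab = "probability density", ...)
  graphics::lines(x$density$r, x$density$fitted, col = 2, lwd = 2)
  invisible(x)
}
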