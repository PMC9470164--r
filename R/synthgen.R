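#' Configuration for single-molecule track and brightness simulations
#'
#' Bundles the parameters of the synthetic single-molecule generator:
#' Poisson arrival of membrane binders, exponential-mixture dwell times,
#' 2D Brownian motion with oligomer-state-dependent diffusivity, a
#' two-state monomer/dimer Markov switch, per-fluorophore chromophore
#' maturation and exponential photobleaching, and Gaussian camera noise.
#'
#' Defaults correspond to a sparsely labelled lipid kinase on a supported
#' bilayer: single-population dwell time 0.453 s, diffusion coefficient
#' 0.148 um^2/s, photobleaching time constant 26.7 s and a chromophore
#' maturation probability of 0.8 for fluorescent-protein tags.
#'
#' @param seed integer root seed; per-operation streams are derived with
#'   [stream_seed()] so stages are independently reproducible.
#' @param frame_interval camera frame interval, seconds.
#' @param n_frames number of frames in the movie.
#' @param field_size width and height of the imaged field, um (length 2).
#' @param arrival_rate membrane binding rate, particles/um^2/s.
#' @param dwell_taus exponential dwell time constants, seconds (1 or 2).
#' @param dwell_fractions mixing fractions of `dwell_taus` (sum to 1).
#' @param diff_coeffs diffusion coefficients, um^2/s, indexed by oligomer
#'   state (element 1 = monomer, element 2 = dimer if present).
#' @param dimer_on_rate,dimer_off_rate monomer->dimer and dimer->monomer
#'   switching rates, 1/s, for the per-particle two-state Markov model.
#' @param maturation_prob probability a fluorophore chromophore matured.
#' @param bleach_tau photobleaching time constant, seconds (`Inf` disables
#'   bleaching).
#' @param monomer_intensity_mean,monomer_intensity_sd mean and camera-noise
#'   SD of a single mature fluorophore, arbitrary units.
#' @param localization_sigma localization noise per axis per frame, um.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_tracks()], [simulate_brightness()]
#' @export
sim_config <- function(seed = 1L,
                       frame_interval = 0.05,
                       n_frames = 400L,
                       field_size = c(20, 20),
                       arrival_rate = 0.05,
                       dwell_taus = 0.453,
                       dwell_fractions = 1,
                       diff_coeffs = 0.148,
                       dimer_on_rate = 0,
                       dimer_off_rate = 1,
                       maturation_prob = 0.8,
                       bleach_tau = 26.7,
                       monomer_intensity_mean = 5500,
                       monomer_intensity_sd = 1100,
                       localization_sigma = 0.02) {
  .check_pos(frame_interval, "frame_interval")
  stopifnot(n_frames >= 1, length(field_size) == 2L, all(field_size > 0))
  if (arrival_rate < 0) stop("`arrival_rate` must be >= 0")
  if (length(dwell_taus) < 1L || any(dwell_taus <= 0))
    stop("`dwell_taus` must all be > 0")
  if (length(dwell_fractions) != length(dwell_taus))
    stop("`dwell_fractions` and `dwell_taus` must have equal length")
  if (abs(sum(dwell_fractions) - 1) > 1e-9)
    stop("`dwell_fractions` must sum to 1")
  if (any(dwell_fractions < 0)) stop("`dwell_fractions` must be >= 0")
  if (any(diff_coeffs <= 0)) stop("`diff_coeffs` must all be > 0")
  if (dimer_on_rate < 0 || dimer_off_rate <= 0)
    stop("dimer switching rates must be non-negative (off rate > 0)")
  if (maturation_prob < 0 || maturation_prob > 1)
    stop("`maturation_prob` must lie in [0, 1]")
  .check_pos(bleach_tau, "bleach_tau", allow_inf = TRUE)
  .check_pos(monomer_intensity_mean, "monomer_intensity_mean")
  if (monomer_intensity_sd < 0) stop("`monomer_intensity_sd` must be >= 0")
  if (localization_sigma < 0) stop("`localization_sigma` must be >= 0")

  cfg <- list(seed = as.integer(seed), frame_interval = frame_interval,
              n_frames = as.integer(n_frames), field_size = field_size,
              arrival_rate = arrival_rate, dwell_taus = dwell_taus,
              dwell_fractions = dwell_fractions, diff_coeffs = diff_coeffs,
              dimer_on_rate = dimer_on_rate, dimer_off_rate = dimer_off_rate,
              maturation_prob = maturation_prob, bleach_tau = bleach_tau,
              monomer_intensity_mean = monomer_intensity_mean,
              monomer_intensity_sd = monomer_intensity_sd,
              localization_sigma = localization_sigma)
  cfg$undersampled <- frame_interval >= min(dwell_taus) / 5
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Single-molecule simulation config\n")
  cat(sprintf("  %d frames at %.3g s; field %g x %g um\n",
              x$n_frames, x$frame_interval, x$field_size[1], x$field_size[2]))
  cat(sprintf("  arrival %.3g /um^2/s; dwell tau(s) %s s; D %s um^2/s\n",
              x$arrival_rate, paste(signif(x$dwell_taus, 3), collapse = "/"),
              paste(signif(x$diff_coeffs, 3), collapse = "/")))
  cat(sprintf("  maturation %.2f; bleach tau %.3g s\n",
              x$maturation_prob, x$bleach_tau))
  invisible(x)
}

#' Draw dwell times from an exponential mixture
#'
#' Direct (continuous, unbinned) draws from the 1- or 2-component
#' exponential dwell model; used both by [simulate_tracks()] and as a
#' clean input for [fit_dwell()] recovery studies.
#'
#' @param n number of draws.
#' @param taus exponential time constants, seconds.
#' @param fractions mixing fractions (sum to 1); default single component.
#' @param seed optional integer seed.
#' @return Numeric vector of dwell times, with attribute `component`
#'   giving the generating component of each draw.
#' @export
simulate_dwells <- function(n, taus, fractions = rep(1 / length(taus), length(taus)),
                            seed = NULL) {
  stopifnot(n >= 0, all(taus > 0), abs(sum(fractions) - 1) < 1e-9)
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(length(taus), n, replace = TRUE, prob = fractions)
  d <- rexp(n, rate = 1 / taus[comp])
  attr(d, "component") <- comp
  d
}

#' Draw 2D Brownian step sizes
#'
#' Per-frame displacements r = sqrt(dx^2 + dy^2) for Brownian motion with
#' diffusion coefficient `D` observed at interval `tau`, optionally from a
#' mixture of diffusive states and with localization noise on each end
#' point (per-axis step variance `2*D*tau + 2*sigma^2`).
#'
#' @param n number of steps.
#' @param D diffusion coefficient(s), um^2/s (length 1 or 2).
#' @param tau frame interval, seconds.
#' @param alpha fraction of the first component when `length(D) == 2`.
#' @param localization_sigma localization noise per axis, um.
#' @param seed optional integer seed.
#' @return Numeric vector of step sizes (um) with attribute `component`.
#' @export
simulate_steps <- function(n, D, tau, alpha = 1, localization_sigma = 0,
                           seed = NULL) {
  stopifnot(n >= 0, all(D > 0), tau > 0, alpha >= 0, alpha <= 1)
  if (!is.null(seed)) set.seed(seed)
  probs <- if (length(D) == 1L) 1 else c(alpha, 1 - alpha)
  comp <- sample.int(length(D), n, replace = TRUE, prob = probs)
  s2 <- 2 * D[comp] * tau + 2 * localization_sigma^2
  r <- sqrt(rnorm(n, sd = sqrt(s2))^2 + rnorm(n, sd = sqrt(s2))^2)
  attr(r, "component") <- comp
  r
}

#' Simulate single-molecule membrane-binding trajectories
#'
#' Generates a table of tracks with the statistical structure assumed by
#' the downstream dwell and step analyses: particles arrive on the field
#' as a Poisson process, draw a dwell time from the exponential mixture in
#' `config`, bleach with time constant `bleach_tau`, and random-walk with
#' the diffusion coefficient of their current oligomer state (a two-state
#' Markov switch when `config$diff_coeffs` has two elements).  The
#' observed lifetime of a particle is `min(dwell, bleach)`.
#'
#' A warning is raised when `frame_interval >= min(dwell_taus)/5`: dwell
#' histograms are then undersampled and short-dwell components cannot be
#' resolved.
#'
#' @param config a [sim_config()].
#' @return A list of class `track_sim` with elements
#'   \describe{
#'     \item{tracks}{data frame with columns `track_id`, `frame`, `t`,
#'       `x`, `y`, `intensity` (one row per particle per frame).}
#'     \item{truth}{per-particle ground truth: arrival time, generating
#'       dwell component, true dwell, bleach time, observed lifetime,
#'       number of mature fluorophores.}
#'     \item{config}{the generating configuration.}
#'   }
#' @export
simulate_tracks <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$undersampled)
    warning("frame_interval >= min(dwell_taus)/5: dwell times are undersampled")
  set.seed(stream_seed(config$seed, "tracks"))

  dt <- config$frame_interval
  t_total <- config$n_frames * dt
  area <- prod(config$field_size)
  n_par <- rpois(1L, config$arrival_rate * area * t_total)
  truth <- data.frame(track_id = integer(), arrival = numeric(),
                      component = integer(), dwell = numeric(),
                      bleach = numeric(), lifetime = numeric(),
                      n_mature = integer())
  if (n_par == 0L) {
    out <- list(tracks = .empty_tracks(), truth = truth, config = config)
    class(out) <- "track_sim"
    return(out)
  }

  arrival <- runif(n_par, 0, t_total)
  comp <- sample.int(length(config$dwell_taus), n_par, replace = TRUE,
                     prob = config$dwell_fractions)
  dwell <- rexp(n_par, rate = 1 / config$dwell_taus[comp])
  bleach <- if (is.finite(config$bleach_tau))
    rexp(n_par, rate = 1 / config$bleach_tau) else rep(Inf, n_par)
  lifetime <- pmin(dwell, bleach)
  n_mature <- 1L + rbinom(n_par, 1L, 0) # monomer tracks: 1 fluorophore
  # maturation gates detectability: immature particles are never seen
  mature <- rbinom(n_par, 1L, config$maturation_prob) == 1L

  two_state <- length(config$diff_coeffs) >= 2L && config$dimer_on_rate > 0

  rows <- vector("list", n_par)
  kept <- logical(n_par)
  for (i in seq_len(n_par)) {
    if (!mature[i]) next
    # frames k (1-based) sampled at t_k = k*dt, visible while bound
    k0 <- ceiling(arrival[i] / dt)
    k0 <- max(k0, 1L)
    k1 <- floor((arrival[i] + lifetime[i]) / dt)
    k1 <- min(k1, config$n_frames)
    if (k1 < k0) next
    nk <- k1 - k0 + 1L
    state <- rep(1L, nk)
    if (two_state) {
      p_on <- 1 - exp(-config$dimer_on_rate * dt)
      p_off <- 1 - exp(-config$dimer_off_rate * dt)
      s <- 1L
      for (k in seq_len(nk)) {
        state[k] <- s
        s <- if (s == 1L) {
          if (runif(1) < p_on) 2L else 1L
        } else {
          if (runif(1) < p_off) 1L else 2L
        }
      }
    }
    Dk <- config$diff_coeffs[pmin(state, length(config$diff_coeffs))]
    sd_step <- sqrt(2 * Dk * dt)
    x0 <- runif(1, 0, config$field_size[1])
    y0 <- runif(1, 0, config$field_size[2])
    x <- x0 + cumsum(c(0, rnorm(nk - 1L, sd = sd_step[-nk])))
    y <- y0 + cumsum(c(0, rnorm(nk - 1L, sd = sd_step[-nk])))
    if (config$localization_sigma > 0) {
      x <- x + rnorm(nk, sd = config$localization_sigma)
      y <- y + rnorm(nk, sd = config$localization_sigma)
    }
    n_fluor <- ifelse(state == 2L, 2L, 1L)
    intensity <- n_fluor * config$monomer_intensity_mean +
      rnorm(nk, sd = config$monomer_intensity_sd * sqrt(n_fluor))
    rows[[i]] <- data.frame(track_id = i, frame = k0:k1,
                            t = (k0:k1) * dt, x = x, y = y,
                            intensity = intensity)
    kept[i] <- TRUE
  }
  tracks <- if (any(kept)) do.call(rbind, rows[kept]) else .empty_tracks()
  rownames(tracks) <- NULL
  truth <- data.frame(track_id = seq_len(n_par), arrival = arrival,
                      component = comp, dwell = dwell, bleach = bleach,
                      lifetime = lifetime, mature = mature,
                      observed = kept)
  out <- list(tracks = tracks, truth = truth, config = config)
  class(out) <- "track_sim"
  out
}

#' @export
print.track_sim <- function(x, ...) {
  cat(sprintf("Synthetic track set: %d observed tracks (%d arrivals), %d rows\n",
              length(unique(x$tracks$track_id)), nrow(x$truth), nrow(x$tracks)))
  invisible(x)
}

#' Simulate per-particle brightness / photobleaching traces
#'
#' Each particle carries 1 (monomer) or 2 (dimer) fluorophores.  Each
#' fluorophore matures independently with probability
#' `config$maturation_prob` and, when `observe_bleaching = TRUE`, bleaches
#' after an exponential time with constant `config$bleach_tau`.  The
#' per-frame intensity is (live mature fluorophores) x
#' `monomer_intensity_mean` plus Gaussian camera noise.  Frame 1 is at
#' t = 0 (illumination start).
#'
#' @param config a [sim_config()].
#' @param oligomer_state `"monomer"` or `"dimer"`.
#' @param n_particles number of particles (>= 1).
#' @param observe_bleaching logical; `FALSE` freezes all fluorophores on.
#' @param n_frames number of frames; defaults to `config$n_frames`.
#' @return A list of class `brightness_sim`: `traces` (data frame
#'   `particle_id`, `frame`, `t`, `intensity`) and `truth` (per particle:
#'   `n_fluor`, `n_mature`, bleach times).
#' @export
simulate_brightness <- function(config, oligomer_state = c("dimer", "monomer"),
                                n_particles, observe_bleaching = TRUE,
                                n_frames = NULL) {
  stopifnot(inherits(config, "sim_config"), n_particles >= 1)
  oligomer_state <- match.arg(oligomer_state)
  if (is.null(n_frames)) n_frames <- config$n_frames
  set.seed(stream_seed(config$seed, "brightness"))

  nf <- if (oligomer_state == "dimer") 2L else 1L
  n_mature <- rbinom(n_particles, nf, config$maturation_prob)
  # bleach times of the mature fluorophores, sorted so that column j is
  # the time at which the j-th bleaching event occurs
  tb <- matrix(Inf, n_particles, nf)
  if (observe_bleaching && is.finite(config$bleach_tau)) {
    for (j in seq_len(nf)) {
      has <- n_mature >= j
      tb[has, j] <- rexp(sum(has), rate = 1 / config$bleach_tau)
    }
    tb <- t(apply(tb, 1L, sort))
    tb <- matrix(tb, n_particles, nf)
  }
  tgrid <- (seq_len(n_frames) - 1L) * config$frame_interval
  live <- matrix(0L, n_particles, n_frames)
  for (j in seq_len(nf)) {
    live <- live + outer(ifelse(n_mature >= j, tb[, j], -Inf), tgrid, ">")
  }
  intensity <- live * config$monomer_intensity_mean
  if (config$monomer_intensity_sd > 0)
    intensity <- intensity + matrix(rnorm(length(live),
                                          sd = config$monomer_intensity_sd),
                                    n_particles, n_frames)
  traces <- data.frame(
    particle_id = rep(seq_len(n_particles), times = n_frames),
    frame = rep(seq_len(n_frames), each = n_particles),
    t = rep(tgrid, each = n_particles),
    intensity = as.vector(intensity))
  traces <- traces[order(traces$particle_id, traces$frame), ]
  rownames(traces) <- NULL
  out <- list(traces = traces,
              truth = data.frame(particle_id = seq_len(n_particles),
                                 n_fluor = nf, n_mature = n_mature,
                                 t_bleach1 = tb[, 1L],
                                 t_bleach2 = if (nf == 2L) tb[, 2L] else NA),
              config = config)
  class(out) <- "brightness_sim"
  out
}

#' Simulate a cooperative binding titration
#'
#' Hill-model surface densities with multiplicative Gaussian noise:
#' `density = Bmax * c^n_H / (Kd^n_H + c^n_H) * (1 + eps)`,
#' `eps ~ N(0, noise_cv)`.
#'
#' @param Bmax saturation surface density, molecules/um^2.
#' @param Kd dissociation constant, nM.
#' @param n_H Hill coefficient.
#' @param concs solution concentrations, nM.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed optional integer seed.
#' @return Data frame `conc_nM`, `density`, `density_true`.
#' @export
simulate_isotherm <- function(Bmax, Kd, n_H, concs, noise_cv = 0, seed = NULL) {
  .check_pos(Kd, "Kd"); .check_pos(n_H, "n_H"); .check_pos(Bmax, "Bmax")
  stopifnot(all(concs >= 0), noise_cv >= 0)
  if (!is.null(seed)) set.seed(stream_seed(seed, "isotherm"))
  mu <- Bmax * concs^n_H / (Kd^n_H + concs^n_H)
  eps <- if (noise_cv > 0) rnorm(length(concs), sd = noise_cv) else 0
  data.frame(conc_nM = concs, density = mu * (1 + eps), density_true = mu)
}

#' Configuration for kinase-phosphatase reaction simulations
#'
#' Parameters of the composition dynamics
#' `dx/dt = k(x) (1 - x) - (p0 + p1 (1 - x)) x` with
#' `k(x) = k0 + k1 x + k2 x^2`, where x is the fraction of PIP lipid in
#' the product (PI(4,5)P2) state.  In stochastic mode the same rates act
#' on a discrete pool of `round(S0 * corral_area)` lipids, and the kinase
#' term is modulated by the fluctuating membrane copy number `N_E(t)`
#' (arrivals at `kinase_kon * kinase_solution_conc * corral_area`,
#' departures at `N_E / kinase_dwell_tau`) relative to its steady-state
#' mean, so that stochastic ensembles converge on the deterministic trace
#' as the corral area grows.
#'
#' @param seed integer root seed.
#' @param S0 total PIP lipid density, lipids/um^2 (default 55555.6, i.e. a
#'   4 mole-percent PIP composition at 0.72 nm^2 per lipid).
#' @param k_coeffs kinase feedback coefficients `c(k0, k1, k2)`, 1/s on
#'   the normalized coordinate.
#' @param phosphatase_coeffs phosphatase coefficients `c(p0, p1)` of the
#'   product-binding feedback form `(p0 + p1 (1 - x)) x`, 1/s.
#' @param corral_area compartment area, um^2.
#' @param kinase_kon kinase membrane on-rate, 1/(nM s um^2).
#' @param kinase_solution_conc kinase solution concentration, nM.
#' @param kinase_dwell_tau mean kinase membrane dwell, seconds.
#' @param x0 initial reaction coordinate in `[0, 1]`.
#' @param t_end simulated time, seconds.
#' @param dt_record recording interval of x(t), seconds (default 2 s, the
#'   acquisition interval of kinetic TIRF movies).
#' @return An object of class `reaction_sim_config`.
#' @export
reaction_sim_config <- function(seed = 1L,
                                S0 = 55555.6,
                                k_coeffs = c(0.001, 0.02, 0.3),
                                phosphatase_coeffs = c(0, 0),
                                corral_area = 25,
                                kinase_kon = 0.1,
                                kinase_solution_conc = 50,
                                kinase_dwell_tau = 2,
                                x0 = 0,
                                t_end = 600,
                                dt_record = 2) {
  .check_pos(S0, "S0"); .check_pos(corral_area, "corral_area")
  .check_pos(dt_record, "dt_record"); .check_pos(t_end, "t_end")
  stopifnot(length(k_coeffs) == 3L, length(phosphatase_coeffs) == 2L,
            all(k_coeffs >= 0), all(phosphatase_coeffs >= 0),
            kinase_kon >= 0, kinase_solution_conc >= 0,
            kinase_dwell_tau > 0, x0 >= 0, x0 <= 1)
  cfg <- list(seed = as.integer(seed), S0 = S0, k_coeffs = k_coeffs,
              phosphatase_coeffs = phosphatase_coeffs,
              corral_area = corral_area, kinase_kon = kinase_kon,
              kinase_solution_conc = kinase_solution_conc,
              kinase_dwell_tau = kinase_dwell_tau, x0 = x0,
              t_end = t_end, dt_record = dt_record)
  class(cfg) <- "reaction_sim_config"
  cfg
}

#' Simulate the kinase-phosphatase composition reaction
#'
#' Deterministic mode integrates
#' `dx/dt = k(x) (1 - x) - (p0 + p1 (1 - x)) x` with [deSolve::ode()].
#' Stochastic mode runs an exact event-driven (Gillespie) simulation over
#' the events kinase arrival, kinase departure, single-lipid
#' phosphorylation and single-lipid dephosphorylation on the discrete
#' lipid pool of one corral, recording `x(t)` and the kinase copy number
#' on the `dt_record` grid.
#'
#' @param config a [reaction_sim_config()].
#' @param mode `"deterministic"` or `"stochastic"`.
#' @return Data frame `t`, `x` (and `n_kinase` for stochastic mode), with
#'   the config attached as attribute `config`.
#' @export
simulate_reaction <- function(config, mode = c("deterministic", "stochastic")) {
  stopifnot(inherits(config, "reaction_sim_config"))
  mode <- match.arg(mode)
  k <- config$k_coeffs; p <- config$phosphatase_coeffs
  times <- seq(0, config$t_end, by = config$dt_record)

  if (mode == "deterministic") {
    rhs <- function(t, y, parms) {
      x <- y[1]
      list((k[1] + k[2] * x + k[3] * x^2) * (1 - x) -
             (p[1] + p[2] * (1 - x)) * x)
    }
    sol <- deSolve::ode(y = c(x = config$x0), times = times, func = rhs,
                        parms = NULL, method = "lsoda")
    out <- data.frame(t = sol[, "time"], x = pmin(pmax(sol[, "x"], 0), 1))
  } else {
    n_lipid <- round(config$S0 * config$corral_area)
    if (n_lipid < 100)
      stop("stochastic mode requires S0 * corral_area >= 100 lipids")
    arr <- config$kinase_kon * config$kinase_solution_conc * config$corral_area
    e_mean <- arr * config$kinase_dwell_tau
    set.seed(stream_seed(config$seed, "reaction"))
    sim <- corral_gillespie_cpp(
      n_lipid = as.integer(n_lipid),
      n_p0 = as.integer(round(config$x0 * n_lipid)),
      k = k, p = p,
      arrival_rate = arr,
      departure_rate = 1 / config$kinase_dwell_tau,
      e_mean = e_mean,
      recruit_coupling = 0,
      t_end = config$t_end, dt_record = config$dt_record)
    out <- data.frame(t = times, x = sim$x, n_kinase = sim$n_kinase)
  }
  attr(out, "config") <- config
  attr(out, "mode") <- mode
  out
}
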