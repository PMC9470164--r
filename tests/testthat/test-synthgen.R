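test_that("config validation rejects impossible parameters", {
  expect_error(sim_config(dwell_taus = -1), "dwell_taus")
  expect_error(sim_config(dwell_taus = c(0.5, 2), dwell_fractions = c(0.6, 0.3)),
               "sum to 1")
  expect_error(sim_config(maturation_prob = 1.2), "maturation_prob")
  expect_error(reaction_sim_config(S0 = -5), "S0")
  expect_true(sim_config(frame_interval = 0.2, dwell_taus = 0.5)$undersampled)
  expect_warning(simulate_tracks(sim_config(frame_interval = 0.2,
                                            dwell_taus = 0.5, n_frames = 50)),
                 "undersampled")
})

test_that("fixed seed makes every generator bit-identical across runs", {
  cfg <- sim_config(seed = 77, n_frames = 100)
  a <- suppressWarnings(simulate_tracks(cfg))
  b <- suppressWarnings(simulate_tracks(cfg))
  expect_identical(a$tracks, b$tracks)
  b1 <- simulate_brightness(cfg, "dimer", 50, n_frames = 20)
  b2 <- simulate_brightness(cfg, "dimer", 50, n_frames = 20)
  expect_identical(b1$traces, b2$traces)
  i1 <- simulate_isotherm(100, 52, 2, c(10, 100), noise_cv = 0.1, seed = 3)
  i2 <- simulate_isotherm(100, 52, 2, c(10, 100), noise_cv = 0.1, seed = 3)
  expect_identical(i1, i2)
  rc <- reaction_sim_config(seed = 5, corral_area = 1, t_end = 100)
  expect_identical(simulate_reaction(rc, "stochastic"),
                   simulate_reaction(rc, "stochastic"))
})

test_that("zero arrival rate yields an empty track table", {
  cfg <- sim_config(arrival_rate = 0, n_frames = 50)
  out <- simulate_tracks(cfg)
  expect_equal(nrow(out$tracks), 0L)
  expect_equal(nrow(out$truth), 0L)
})

test_that("dwell mixture draws have the closed-form mixture mean", {
  d <- simulate_dwells(1e5, taus = c(0.5, 2.0), fractions = c(0.7, 0.3),
                       seed = 11)
  # mixture mean 0.7*0.5 + 0.3*2.0 = 0.95; MC error ~ sd/sqrt(n)
  mix_sd <- sqrt(0.7 * (2 * 0.5^2) + 0.3 * (2 * 2^2) - 0.95^2)
  expect_lt(abs(mean(d) - 0.95), 4 * mix_sd / sqrt(1e5))
})

test_that("simulated track dwells follow the discretized exponential law", {
  # Observed span in frames is floor(phi + T/dt) for uniform arrival
  # phase phi, so conditional on being observed at all (span >= 1) the
  # survival of the extracted dwell at the bin edges is exactly
  # exp(-k dt / tau); bleaching disabled.
  tau <- 0.453; dt <- 0.01
  cfg <- sim_config(seed = 3, frame_interval = dt, n_frames = 4000,
                    field_size = c(10, 10), arrival_rate = 2.5,
                    dwell_taus = tau, bleach_tau = Inf, maturation_prob = 1)
  out <- simulate_tracks(cfg)
  dw <- extract_dwells(out$tracks, dt)
  expect_gt(length(dw), 5000)
  ks <- seq_len(ceiling(max(dw) / dt))
  emp <- vapply(ks, function(k) mean(dw > k * dt + 1e-9), numeric(1))
  expect_lt(max(abs(emp - exp(-ks * dt / tau))), 0.02)
})

test_that("per-frame MSD equals 4 D tau + 4 sigma_loc^2", {
  cfg <- sim_config(seed = 9, arrival_rate = 0.4, n_frames = 400,
                    diff_coeffs = 0.148, bleach_tau = Inf,
                    maturation_prob = 1, localization_sigma = 0.02)
  out <- simulate_tracks(cfg)
  r <- extract_steps(out$tracks)
  expect_gt(length(r), 2e4)
  expected <- 4 * 0.148 * cfg$frame_interval + 4 * 0.02^2
  expect_lt(abs(mean(r^2) - expected) / expected, 0.02)
})

test_that("dimer brightness honours maturation and bleaching statistics", {
  # all-mature, noise-free dimers start at exactly twice the monomer mean
  cfg <- sim_config(seed = 4, maturation_prob = 1, monomer_intensity_sd = 0)
  b <- simulate_brightness(cfg, "dimer", 200, n_frames = 5)
  first <- b$traces[b$traces$frame == 1, ]
  expect_true(all(first$intensity == 2 * cfg$monomer_intensity_mean))

  # with maturation p, two-visible fraction among detectable dimers is
  # p^2 / (1 - (1-p)^2)
  cfg2 <- sim_config(seed = 5, maturation_prob = 0.8)
  b2 <- simulate_brightness(cfg2, "dimer", 4e4, n_frames = 2)
  f0 <- b2$traces[b2$traces$frame == 1, ]
  detectable <- f0$intensity >= 0.5 * cfg2$monomer_intensity_mean
  two <- f0$intensity >= 1.5 * cfg2$monomer_intensity_mean
  p <- 0.8
  expected <- p^2 / (1 - (1 - p)^2)
  expect_lt(abs(mean(two[detectable]) - expected), 0.01)

  # both-mature dimers: two-visible survival is exp(-2 t / tau_bleach)
  cfg3 <- sim_config(seed = 6, maturation_prob = 1, monomer_intensity_sd = 0,
                     bleach_tau = 10, frame_interval = 0.5)
  b3 <- simulate_brightness(cfg3, "dimer", 2e4, n_frames = 40)
  tr <- b3$traces
  surv <- tapply(tr$intensity >= 1.5 * cfg3$monomer_intensity_mean, tr$t, mean)
  tgrid <- as.numeric(names(surv))
  expect_lt(max(abs(surv - exp(-2 * tgrid / 10))), 0.02)
})

test_that("isotherm generator satisfies Hill-curve identities", {
  iso <- simulate_isotherm(100, Kd = 52, n_H = 1, concs = c(52, 1e7),
                           noise_cv = 0)
  expect_equal(iso$density[1], 50)        # half saturation at c = Kd
  expect_equal(iso$density[2], 100, tolerance = 1e-4)  # saturation limit
  iso2 <- simulate_isotherm(100, Kd = 52, n_H = 2, concs = c(52, 26),
                            noise_cv = 0)
  expect_equal(iso2$density[1] / iso2$density[2], 2.5, tolerance = 1e-12)
})

test_that("deterministic reaction matches first-order closed form", {
  cfg <- reaction_sim_config(k_coeffs = c(0.01, 0, 0), t_end = 400)
  det <- simulate_reaction(cfg, "deterministic")
  expect_lt(max(abs(det$x - (1 - exp(-0.01 * det$t)))), 1e-5)
  # no phosphatase: x(t) is monotone and ends near 1
  cfg2 <- reaction_sim_config(k_coeffs = c(0.001, 0.02, 0.3), t_end = 600)
  det2 <- simulate_reaction(cfg2, "deterministic")
  expect_true(all(diff(det2$x) > -1e-10))
  expect_gt(det2$x[length(det2$x)], 0.99)
})

test_that("stochastic mode guards lipid granularity and keeps x in [0,1]", {
  expect_error(simulate_reaction(
    reaction_sim_config(S0 = 500, corral_area = 0.1), "stochastic"),
    ">= 100 lipids")
  sto <- simulate_reaction(reaction_sim_config(seed = 8, corral_area = 1,
                                               t_end = 200), "stochastic")
  expect_true(all(sto$x >= 0 & sto$x <= 1))
  expect_true(all(sto$n_kinase >= 0))
})

test_that("time-to-half-maximum varies more in small corrals", {
  half_var <- function(area, seed) {
    hs <- vapply(1:30, function(i) {
      cfg <- reaction_sim_config(seed = stream_seed(seed, "rep", i),
                                 corral_area = area, t_end = 300)
      tr <- simulate_reaction(cfg, "stochastic")
      half_time(tr$t, tr$x)
    }, numeric(1))
    stats::var(hs)
  }
  expect_gt(half_var(1, 41), half_var(25, 42))
})
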