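test_that("reaction coordinate normalization anchors start to 0 and end to 1", {
  t <- 0:20
  x <- c(seq(0, 1, length.out = 18), 1, 1, 1)
  expect_equal(normalize_reaction_coordinate(t, x), x, tolerance = 1e-12)
  # linear ramp 100 -> 300: midpoint maps to 0.5 (no plateau: warned)
  t2 <- seq(0, 10, by = 0.5)
  expect_warning(x2 <- normalize_reaction_coordinate(t2, 100 + 20 * t2),
                 "plateaued")
  expect_equal(x2[t2 == 5], 0.5)
  # generator round trip, noise-free
  det <- simulate_reaction(reaction_sim_config(t_end = 600), "deterministic")
  I <- 200 + 5000 * det$x
  expect_lt(max(abs(normalize_reaction_coordinate(det$t, I) - det$x)), 1e-6)
  expect_warning(
    normalize_reaction_coordinate(0:10, c(0:9, 20) / 20), "plateaued")
})

test_that("windowed regression slope is exact for lines and quadratics", {
  t <- seq(0, 20, by = 0.5)
  expect_equal(as.numeric(local_rate(t, 0.03 * t + 2)),
               rep(0.03, length(t)), tolerance = 1e-12)
  # centered linear regression of a quadratic recovers the tangent slope
  a <- 0.02
  sl <- local_rate(t, a * t^2, halfwidth = 2)
  interior <- !attr(sl, "one_sided")
  expect_equal(as.numeric(sl[interior]), 2 * a * t[interior],
               tolerance = 1e-10)
  expect_true(any(attr(sl, "one_sided")))
  # white noise: slopes average to zero
  set.seed(4)
  z <- local_rate(seq(0, 500, 2), rnorm(251))
  expect_lt(abs(mean(z)), 0.01)
})

test_that("per-enzyme velocity divides the local rate by enzyme density", {
  t <- seq(0, 100, by = 2)
  P <- 0.027 * t
  v <- per_enzyme_velocity(t, P, E = 10, S0 = 55555.6)
  expect_equal(v$v, rep(2.7e-3, length(t)), tolerance = 1e-10)
  expect_equal(v$S, 55555.6 - P)
  # doubling E halves v; zero slope gives zero v
  v2 <- per_enzyme_velocity(t, P, E = 20, S0 = 55555.6)
  expect_equal(v2$v, v$v / 2)
  v0 <- per_enzyme_velocity(t, rep(5, length(t)), E = 10, S0 = 55555.6)
  expect_equal(v0$v, rep(0, length(t)))
  # enzyme density below the floor is masked, not divided
  E <- rep(10, length(t)); E[3] <- 0.01
  vm <- per_enzyme_velocity(t, P, E, S0 = 55555.6)
  expect_true(is.na(vm$v[3]) && vm$masked[3])
})

test_that("velocity is invariant to the raw intensity scale under calibration", {
  t <- seq(0, 100, by = 2)
  P <- 30 * t  # product density, lipids/um^2
  cal_a <- build_calibration(c(100, 1000, 3000), c(100, 1000, 3000) * 2 + 50)
  cal_b <- build_calibration(c(100, 1000, 3000), c(100, 1000, 3000) * 9 + 400)
  Ia <- intensity_from_density(cal_a, P)
  Ib <- intensity_from_density(cal_b, P)
  va <- per_enzyme_velocity(t, predict(cal_a, Ia), E = 10, S0 = 55555.6)
  vb <- per_enzyme_velocity(t, predict(cal_b, Ib), E = 10, S0 = 55555.6)
  expect_equal(va$v, vb$v, tolerance = 1e-9)
})

test_that("feedback coefficients are recovered from noise-free traces", {
  k <- c(0.001, 0.02, 0.3)
  det <- simulate_reaction(reaction_sim_config(k_coeffs = k, t_end = 300),
                           "deterministic")
  f <- fit_feedback(det$t, det$x)
  expect_equal(f$order, 2L)
  expect_lt(abs(f$k0 - k[1]) / k[1], 0.02)
  expect_lt(abs(f$k1 - k[2]) / k[2], 0.02)
  expect_lt(abs(f$k2 - k[3]) / k[3], 0.02)
  expect_false(f$unphysical)
})

test_that("order selection distinguishes first- from second-order feedback", {
  det1 <- simulate_reaction(reaction_sim_config(k_coeffs = c(0.005, 0.1, 0),
                                                t_end = 300, dt_record = 0.5),
                            "deterministic")
  f1 <- fit_feedback(det1$t, det1$x, halfwidth = 1)
  expect_equal(f1$order, 1L)
  expect_equal(f1$k2, 0)
  # nested-model consistency: forcing order 2 on first-order data gives
  # a negligible quadratic coefficient
  f1b <- fit_feedback(det1$t, det1$x, model_order = 2, halfwidth = 1)
  expect_lt(abs(f1b$k2), 0.05 * f1b$k1)

  n_correct <- 0L
  for (i in 1:40) {
    k2 <- if (i %% 2 == 0) 0.3 else 0
    det <- simulate_reaction(reaction_sim_config(k_coeffs = c(0.005, 0.1, k2),
                                                 t_end = 300, dt_record = 0.5),
                             "deterministic")
    set.seed(1200 + i)
    xn <- det$x + rnorm(length(det$x), 0, 0.01)
    f <- suppressWarnings(
      fit_feedback(det$t, xn, halfwidth = 1, refine = FALSE))
    n_correct <- n_correct + ((f$order == 2L) == (k2 > 0))
  }
  expect_gte(n_correct / 40, 0.95)
})

test_that("coefficient recovery stays within 10% at 1% trace noise", {
  k <- c(0.001, 0.02, 0.3)
  det <- simulate_reaction(reaction_sim_config(k_coeffs = k, t_end = 300,
                                               dt_record = 0.5),
                           "deterministic")
  errs <- vapply(1:20, function(i) {
    set.seed(1500 + i)
    xn <- det$x + rnorm(length(det$x), 0, 0.01)
    f <- fit_feedback(det$t, xn, model_order = 2, halfwidth = 1)
    abs(c(f$k0 - k[1], f$k1 - k[2], f$k2 - k[3])) / k
  }, numeric(3))
  expect_lt(median(errs[1, ]), 0.10)
  expect_lt(median(errs[2, ]), 0.10)
  expect_lt(median(errs[3, ]), 0.10)
})

test_that("self-consistency: integrating fitted coefficients reproduces the trace", {
  k <- c(0.002, 0.03, 0.25)
  det <- simulate_reaction(reaction_sim_config(k_coeffs = k, t_end = 400,
                                               dt_record = 0.5),
                           "deterministic")
  f <- fit_feedback(det$t, det$x, halfwidth = 0.5)
  redo <- simulate_reaction(
    reaction_sim_config(k_coeffs = c(f$k0, f$k1, f$k2), t_end = 400,
                        dt_record = 0.5), "deterministic")
  expect_lt(max(abs(redo$x - det$x)), 0.02)
})

test_that("half-time interpolates the first crossing of x = 0.5", {
  t <- seq(0, 10, by = 1)
  expect_equal(half_time(t, t / 10), 5)
  tt <- seq(0, 60, by = 0.5)
  expect_equal(half_time(tt, 1 / (1 + exp(-(tt - 30) / 4))), 30,
               tolerance = 1e-6)
  expect_true(is.na(half_time(tt, rep(0.2, length(tt)))))
})
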