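test_that("phosphatase-free models have the single stable state x = 1", {
  m <- competition_model(c(0.01, 0.05, 0), c(0, 0))
  ss <- find_steady_states(m)
  stable <- ss[ss$stable, ]
  expect_equal(nrow(stable), 1L)
  expect_equal(stable$x, 1)
})

test_that("the symmetric linear cancellation is flagged as degenerate", {
  m <- competition_model(c(0, 0.2, 0), c(0, 0.2))
  expect_warning(ss <- find_steady_states(m), "continuum")
  expect_true(attr(ss, "degenerate"))
  expect_equal(nrow(ss), 0L)
})

test_that("roots agree with a dense sign-scan oracle on random models", {
  grid <- seq(0, 1, length.out = 10001)
  set.seed(99)
  n_bad <- 0L
  for (i in 1:100) {
    m <- competition_model(k_coeffs = runif(3, 0, 0.5),
                           phosphatase_coeffs = runif(2, 0, 0.5))
    ss <- find_steady_states(m)
    g <- (m$k[1] + m$k[2] * grid + m$k[3] * grid^2) * (1 - grid) -
      (m$p[1] + m$p[2] * (1 - grid)) * grid
    sgn <- sign(g)
    flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    scan_roots <- (grid[flips] + grid[flips + 1]) / 2
    # boundary roots the interior sign scan cannot see
    if (abs(g[1]) < 1e-12) scan_roots <- c(0, scan_roots)
    if (abs(g[length(g)]) < 1e-12) scan_roots <- c(scan_roots, 1)
    ok <- length(scan_roots) == nrow(ss) &&
      (nrow(ss) == 0 || max(abs(sort(scan_roots) - ss$x)) < 2e-4)
    n_bad <- n_bad + !ok
  }
  expect_equal(n_bad, 0L)
})

test_that("second-order feedback widens the bistable phosphatase range", {
  kwt <- c(0.001, 0.02, 0.3)
  klin <- c(0.001, 0.02 + 2 * 0.3 / 3, 0)  # same mean k(x) on [0, 1]
  rw <- bistable_range(competition_model(kwt, c(0, 0.05)), "p0", 0, 0.5)
  rl <- bistable_range(competition_model(klin, c(0, 0.05)), "p0", 0, 0.5)
  expect_equal(length(rw), 2L)
  expect_gt(diff(rw), 0)
  # matched linear model: empty (or strictly contained) interval
  if (length(rl) == 2L) {
    expect_gt(rl[1], rw[1])
    expect_lt(rl[2], rw[2])
  } else {
    expect_equal(length(rl), 0L)
  }
  # the interval edges bracket a saddle-node: stable-state count drops
  # from >= 2 inside to < 2 just outside
  n_stable_at <- function(p0) {
    m <- competition_model(kwt, c(p0, 0.05))
    sum(find_steady_states(m)$stable)
  }
  eps <- 1e-4
  expect_gte(n_stable_at(mean(rw)), 2)
  expect_lt(n_stable_at(rw[2] + eps), 2)
  expect_lt(n_stable_at(rw[1] - eps), 2)
})

test_that("a sweep with no kinase activity has an empty bistable range", {
  m <- competition_model(c(0, 0, 0), c(0.05, 0.05))
  expect_equal(length(bistable_range(m, "p0", 0.001, 0.5)), 0L)
})

test_that("corral trajectories conserve composition bounds and respond to kinase", {
  m <- competition_model(c(0.001, 0.02, 0.3), c(0.01, 0), corral_area = 1)
  ens <- run_corral_ensemble(m, 10, seed = 12, t_end = 200, x0 = 0.2)
  expect_true(all(ens$trajectories$x >= 0 & ens$trajectories$x <= 1))
  expect_true(all(ens$trajectories$n_kinase >= 0))
  # zero kinase arrival and no phosphatase: corrals stay at x0
  m0 <- competition_model(c(0.01, 0.02, 0.3), c(0, 0), corral_area = 1,
                          kinase_solution_conc = 0)
  e0 <- suppressWarnings(run_corral_ensemble(m0, 5, seed = 13, t_end = 100,
                                             x0 = 0.25))
  expect_true(all(e0$trajectories$x == 0.25))
})

test_that("stochastic corral means converge on the deterministic trace", {
  m <- competition_model(c(0.001, 0.02, 0.3), c(0, 0), corral_area = 25)
  ens <- run_corral_ensemble(m, 200, seed = 2, t_end = 400, x0 = 0)
  xm <- tapply(ens$trajectories$x, ens$trajectories$t, mean)
  det <- simulate_reaction(
    reaction_sim_config(k_coeffs = c(0.001, 0.02, 0.3), t_end = 400),
    "deterministic")
  expect_lt(max(abs(xm - det$x)), 0.03)
})

test_that("completion-time variation decreases with corral area", {
  m1 <- competition_model(c(0.001, 0.02, 0.3), c(0, 0), corral_area = 1)
  m25 <- competition_model(c(0.001, 0.02, 0.3), c(0, 0), corral_area = 25)
  e1 <- run_corral_ensemble(m1, 50, seed = 7, t_end = 400, x0 = 0)
  e25 <- run_corral_ensemble(m25, 50, seed = 7, t_end = 400, x0 = 0)
  expect_gt(e1$cv_completion, e25$cv_completion)
})

test_that("outcome fraction moves monotonically with corral area", {
  # bistable model started at the unstable side: large corrals follow the
  # deterministic outcome, small corrals scatter across the separatrix
  m <- competition_model(c(0.001, 0.02, 0.3), c(0.07, 0),
                         kinase_solution_conc = 5)
  gs <- geometry_sensing_scan(m, areas = c(1, 4), n_corrals = 30, seed = 4,
                              t_end = 300, x0 = 0.5)
  expect_equal(nrow(gs), 2L)
  expect_true(all(gs$fraction_product >= 0 & gs$fraction_product <= 1))
  expect_lte(gs$fraction_product[1], gs$fraction_product[2])
  expect_true(all(gs$ci_lo <= gs$fraction_product &
                    gs$fraction_product <= gs$ci_hi))
})

test_that("tiny corral areas below the lipid guard error out", {
  m <- competition_model(c(0.01, 0, 0), c(0, 0), corral_area = 0.001,
                         S_total = 5000)
  expect_error(run_corral_ensemble(m, 2, seed = 1, t_end = 10), "100 lipids")
})
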