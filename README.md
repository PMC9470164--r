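# memkin — single-molecule membrane binding and lipid kinase kinetics

`memkin` is an R package for analysing the quantitative observables of
single-molecule TIRF experiments on peripheral membrane enzymes —
prototypically the lipid kinase PIP5K, which binds PI(4,5)P₂-containing
supported bilayers, dimerizes on the membrane, and phosphorylates
PI(4)P with strong positive feedback.  It is written for biophysicists
who export trajectories and intensity traces from spot-tracking software
and want reproducible, testable implementations of the standard analyses:

* **Dwell-time survival fits** — log₁₀(1 − CDF) binned at the frame
  interval, fit to `exp(-t/τ)` or the two-population mixture
  `α·exp(-t/τ₁) + (1-α)·exp(-t/τ₂)`, with principled model selection
  (R² gate + F-test), optional photobleaching correction
  `1/τ_obs = 1/τ_true + 1/τ_bleach`, and an independent EM mixture fit
  as cross-check.
* **Step-size (diffusion) fits** — probability-density histograms of 2D
  displacements fit to the Brownian form
  `f(r) = r/(2Dτ)·exp(−r²/4Dτ)` and its two-species mixture
  (monomer/dimer mobility).
* **Oligomer brightness** — dimer classification by molecular
  brightness, stepwise photobleaching counting (change-point detection),
  time-resolved dimer fractions, attachment-vs-equilibrium brightness.
* **Surface density and cooperativity** — fluorescence calibration to
  molecules/µm² with dye scaling factors, lipid footprint conversion
  (4 mole-% at 0.72 nm²/lipid = 55,556 lipids/µm²), and Hill isotherm
  fits `ρ(c) = B_max·c^n_H/(K_d^n_H + c^n_H)`.
* **Feedback kinetics** — reaction coordinate normalization, ±2 s
  windowed-regression derivatives, per-enzyme velocity
  `v_molecule = (dP/dt)/E(t)`, and decomposition of the composition
  dynamics `dx/dt = (k₀ + k₁x + k₂x²)(1−x)` into feedback orders
  (second order ⇔ membrane-mediated dimerization).
* **Bistable kinase–phosphatase competition** — exhaustive steady-state
  and bistable-range analysis of
  `g(x) = k(x)(1−x) − (p₀ + p₁(1−x))x`, plus exact Gillespie ensembles
  of micron-scale membrane corrals (C++ core) exhibiting trajectory
  heterogeneity and stochastic geometry sensing.
* **Synthetic data generators** for all of the above with known ground
  truth (Poisson arrivals, exponential-mixture dwells, state-dependent
  Brownian motion, ~80% chromophore maturation, exponential bleaching,
  camera noise, cooperative isotherms, composition-dependent reaction
  traces with kinase copy-number noise).

## Worked example

Simulate a single-molecule movie, run the trajectory pipeline, and fit
the two primitive observables:

```r
library(memkin)

cfg <- sim_config(seed = 42, arrival_rate = 0.5, n_frames = 1000)
sim  <- simulate_tracks(cfg)
filt <- filter_tracks(sim$tracks, movie_n_frames = 1000,
                      field_bounds = cfg$field_size)
filt$report
#> Track filter: 7504 in -> 4810 out
#>   removed by track_start: 6
#>   removed by track_end:   64
#>   removed by duration:    1490
#>   removed by immobile:    1
#>   removed by edge:        1133

fit_dwell(extract_dwells(filt$tracks, cfg$frame_interval),
          cfg$frame_interval)
#> Dwell-time fit (1 component, N = 4810)
#>   tau = 0.4603 s   (R2 = 0.9965 in log-survival space)

fit_steps(extract_steps(filt$tracks), cfg$frame_interval)
#> Step-size fit (1 component, 50360 steps at 0.05 s)
#>   D = 0.1563 um^2/s   (R2 = 0.9988)
```

The generator used τ = 0.453 s and D = 0.148 µm²/s.  The fitted dwell
(0.460 s) reflects the bleaching competition built into the movie
(τ_bleach = 26.7 s shortens observed dwells; `correct_bleaching()`
inverts it), and the fitted D is inflated by exactly the localization
noise term 4σ_loc²: 0.148 + 0.02²/0.05 = 0.156 µm²/s.

Cooperative binding and feedback decomposition:

```r
iso <- simulate_isotherm(350, Kd = 52, n_H = 2,
                         concs = exp(seq(log(2), log(2000), length.out = 12)),
                         noise_cv = 0.05, seed = 42)
fit_hill(iso$conc_nM, iso$density)
#> Hill isotherm fit: Bmax = 362.4 /um^2, Kd = 55.55 nM, n_H = 1.88
#>   SE: Bmax 4.36, Kd 1.98, n_H 0.107

det <- simulate_reaction(reaction_sim_config(k_coeffs = c(0.001, 0.02, 0.3),
                                             t_end = 300), "deterministic")
fit_feedback(det$t, det$x)
#> Feedback fit (order 2, 33 points): dx/dt = k(x)(1-x)
#>   k(x) = 0.0009998 + 0.02 x + 0.3 x^2
half_time(det$t, det$x)
#> [1] 68.3
```

The order-2 selection (a nonzero `k₂` term) is the kinetic signature of
membrane-mediated dimerization; a dimerization-deficient enzyme fits the
first-order law `(k₀ + k₁x)(1−x)`.

See `vignettes/membrane-kinase-kinetics.Rmd` for the models, their
assumptions, parameter defaults and numerical choices.

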