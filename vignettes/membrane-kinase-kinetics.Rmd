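---
title: "Models and methods for single-molecule membrane-kinase kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for single-molecule membrane-kinase kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memkin)
```

# Scope

`memkin` analyses the observables of single-molecule TIRF experiments on
peripheral membrane enzymes, with the lipid kinase PIP5K (which
phosphorylates PI(4)P to PI(4,5)P2 and can dimerize on the membrane) as
the motivating system.  Five questions drive the design:

1. How long do single enzymes stay membrane-bound, and is the dwell-time
   distribution one exponential population or a mixture?
2. How fast do they diffuse, and does the step-size distribution require
   one or two diffusive species (monomer vs dimer)?
3. What oligomeric state do molecules occupy, read out from molecular
   brightness and stepwise photobleaching?
4. How cooperative is membrane binding, on an absolute surface-density
   scale (molecules/µm²)?
5. What feedback order governs the lipid phosphorylation kinetics, and
   when does the kinase–phosphatase competition become bistable —
   deterministically or only through stochastic fluctuations in small
   membrane corrals?

Because no deposited single-molecule data accompany this class of
experiment, a first-class synthetic-data generator reproduces the
statistical structure of each observable with known ground truth, and
every analysis stage is validated against it.

# Dwell-time survival analysis

A membrane-binding event observed at frame interval $\tau_f$ yields a
dwell equal to its observed frame span times $\tau_f$.  `fit_dwell()`
builds the empirical $1-\mathrm{CDF}$ binned at the frame interval and
fits, in $\log_{10}$-survival space,

$$f(t) = e^{-t/\tau} \quad\text{or}\quad
  f(t) = \alpha e^{-t/\tau_1} + (1-\alpha) e^{-t/\tau_2},$$

escalating to two components only when the single fit is of low quality.
"Low quality" is not standardized in the field, so the package makes it
explicit and configurable: escalate when the single-exponential $R^2$ in
log-survival space (over the first three decades) falls below 0.99 *and*
an F-test against the two-component model is significant at $p < 0.01$.
Two further numerical choices:

* **First-bin truncation.** Dwells shorter than one frame are
  unobservable; the survival curve is fitted from the second bin onward.
  Because the survival estimate itself uses the full sample, no
  amplitude parameter is needed.
* **Degenerate collapse.** A two-component fit with
  $|\tau_2-\tau_1|/\tau_2 < 0.1$ or $\alpha$ within 0.01 of 0 or 1
  collapses to one component.

**Convention:** components are ordered $\tau_1 \le \tau_2$ and $\alpha$
is the fraction of the *fast*-dissociating component $\tau_1$ (the same
convention applies to step fits, where $\alpha$ belongs to the slow
diffusive species $D_1 \le D_2$).  Published tables are not always
internally explicit about this; the package fixes the convention and
documents it rather than guessing per dataset.

An independent maximum-likelihood mixture fit (`fit_dwell_mle()`, EM on
the raw unbinned dwells) is provided as a cross-check, not as the
default, so the two routes can disagree informatively in tests.

Photobleaching competes with unbinding, so observed rates add:
$1/\tau_{obs} = 1/\tau_{true} + 1/\tau_{bleach}$.
`correct_bleaching()` inverts this per component; it is off by default
because published dwell values are not always bleach-corrected, and it
refuses $\tau_{obs} \ge \tau_{bleach}$, where unbinding is unresolvable.

# Step-size mixture fitting

For 2D Brownian motion the per-frame displacement density is the
Rayleigh form

$$f(r) = \frac{r}{2D\tau} e^{-r^2/4D\tau},$$

with the two-species mixture $\alpha f(r;D_1) + (1-\alpha) f(r;D_2)$.
`fit_steps()` builds the probability-density histogram (bin width
0.01 µm; density = frequency / bin width) and least-squares fits with
trust-region optimization, multi-started over $\alpha \in
\{0.2, 0.5, 0.8\}$ and moment-based $D$ initializations to avoid local
minima; ties go to the lowest residual, then the fewer components.  The
escalation rule is identical to the dwell fit.  The moment estimator
$\hat D = \overline{r^2}/4\tau$ is the independent oracle used in tests.
Localization noise adds $4\sigma_{loc}^2$ to the per-frame MSD; with the
default $\sigma_{loc} = 0.02$ µm this inflates an apparent
$D \approx 0.15$ µm²/s by about 5% at 50 ms frames.  It is deliberately
not subtracted (matching common practice), so pipeline-level recoveries
are asserted against $D + \sigma_{loc}^2/\tau$, while sample-level fits
on noise-free draws recover $D$ itself.

# Brightness, photobleaching steps and oligomer state

A dimer carries two fluorophores, but each fluorophore is fluorescent
only with the chromophore maturation probability $p$ (~0.8 for
fluorescent-protein tags).  Among *detectable* dimers (at least one
mature fluorophore) the fraction showing two-fluorophore brightness is

$$\frac{p^2}{1-(1-p)^2} = \frac{2}{3} \text{ at } p = 0.8,$$

which is the quantitative anchor for the attachment-brightness analysis.
Note a real experimental subtlety the package surfaces but cannot
resolve: if an instrument reports an initial "dimer fraction" of ~0.8 at
$p \approx 0.8$, that is inconsistent with the independent-maturation
arithmetic above; the discrepancy depends on whether classification used
a brightness threshold or two visible bleach steps.

The fixed classification threshold (default 8200 A.U.) is
instrument-specific; `brightness_threshold()` offers an automatic
alternative at the antimode between fitted one- and two-fluorophore
Gaussian components.

`count_bleach_steps()` detects intensity change points by binary
segmentation into piecewise-constant levels with a BIC stopping rule,
then keeps level changes of magnitude $\ge 3\,\sigma_{noise}$ separated
by $\ge 2$ frames.  This was chosen over HMM-style methods because it is
robust on short traces and needs no training; its failure mode (merging
two bleach events that occur within the minimum separation) is handled
in validation by conditioning on resolvable event spacing.

Under continuous illumination, both-mature dimers lose their second
fluorophore as the minimum of two exponential clocks, so the two-visible
fraction among initially two-visible particles decays as
$e^{-2t/\tau_{bleach}}$ — the analytic curve used to validate the
time-resolved dimer-fraction estimator.  With membrane binding switched
on, new arrivals keep the late-time dimer fraction above this curve,
which is why experimental time courses plateau.

# Surface-density calibration and cooperativity

Fluorescence is converted to absolute density via a linear standard
curve (lipid standards of known density, or an FCS-calibrated protein
series), with a dye scaling factor — the ratio of the probe dye's and
standard dye's solution brightness slopes — when the two differ:
$\rho(I) = (I - b) / (m \cdot s)$.  The intercept is fitted, not forced
through zero, because background fluorescence exists.

The footprint conversion treats a mole fraction as
$\rho = x / a_{lipid}$ with $a_{lipid} = 0.72$ nm² and **no
factor-of-two leaflet split** — 4 mole-percent gives 55,556 lipids/µm².
This matches the convention used when kinetic traces are anchored to
"all PIP converted"; halving it for leaflet-resolved work is a caller
decision.

Cooperative binding isotherms use the concerted (Hill) model
$\rho(c) = B_{max} c^{n_H} / (K_d^{n_H} + c^{n_H})$, weighted by inverse
replicate variance when available.  Titrations whose maximum density
stays below 70% of the fitted $B_{max}$ are flagged as extrapolated.
`fit_hill(..., fix_n_H = 1)` exposes the non-cooperative reference
model; on cooperative data its residuals show systematic sign runs,
which is the package's misfit diagnostic.

# Feedback kinetics

Reaction traces (sensor intensity at 2 s intervals) are normalized to
the reaction coordinate $x \in [0,1]$ using the first sample and the
plateau mean as anchors (falling back to the final sample, with a
warning, when no plateau exists).  The sensor is assumed linear in
product density between these anchors; sensor-binding nonlinearity is
out of scope and would bias $k(x)$ shapes, not orders.

Derivatives use the field's windowed linear regression (±2 s by
default).  The composition dynamics are modeled as

$$\frac{dx}{dt} = k(x)\,(1-x), \qquad k(x) = k_0 + k_1 x + k_2 x^2,$$

and the feedback *order* is selected on the derivative-space regression
(basis $(1-x), x(1-x), x^2(1-x)$ over $x \in (0.02, 0.98)$, where
$(1-x)$ does not amplify noise) by an F-test at $p<0.01$ plus a
practical-significance guard: $|k_2|$ must exceed 2% of the total rate
amplitude, so a statistically detectable but kinetically negligible
curvature stays first order.  Second order is the signature of
membrane-mediated dimerization; first order corresponds to simple
product binding.

Windowed-regression differentiation of a ±2 s window carries an
$O((k h)^2)$ slope bias (~3% at the default conditions) and amplifies
noise, both of which project disproportionately onto the small
coefficients $k_0, k_1$.  The package therefore refines the
coefficients of the selected order by **trajectory least squares** —
integrating the rate law and minimizing
$\sum_i (x_{model}(t_i) - x_i)^2$ over the coefficients and the initial
composition, initialized from the derivative-based estimates.  This
recovers noise-free coefficients essentially exactly at 2 s sampling and
keeps median errors below 10% at 1% trace noise; `refine = FALSE`
restores the pure derivative-space fit.

Per-enzyme velocity is $v_{molecule}(t) = (dP/dt)\,/\,E(t)$ with
substrate $S(t) = S_0 - P(t)$; points with enzyme density below
0.05 molecules/µm² are masked rather than divided.  The velocity-vs-$S$
relation is reported as the linear-regime slope; the package flags
curvature rather than committing to a saturating form, which the
available data do not constrain.

# Bistable kinase–phosphatase competition in corrals

The competition model is

$$\frac{dx}{dt} = g(x) = (k_0 + k_1 x + k_2 x^2)(1-x) -
  (p_0 + p_1 (1-x))\,x.$$

The phosphatase feedback form $(p_0 + p_1(1-x))x$ is a design choice:
its product is PI(4)P ($1-x$), its feedback is stated only as
"product-binding", and the minimal form mirroring the kinase's
first-order term is adopted.  No quantitative phosphatase rate constants
exist to recover, so $p_0, p_1$ are free parameters.

$g$ is a polynomial of degree ≤ 3, so `find_steady_states()` is
exhaustive via `polyroot()`, with stability from the sign of $g'$ and an
explicit degenerate flag for the identically-zero cancellation case.
`bistable_range()` grid-scans one parameter and bisects the interval
edges, which are saddle-node bifurcations.  A useful structural fact:
with $k_2 = 0$ the right-hand side is quadratic and cannot have two
stable interior states, so a first-order kinase has no deterministic
bistable range against this phosphatase — bistability of the
dimerization-deficient mutant can only be stochastic.

Stochastic corrals use an exact Gillespie simulation (implemented in
C++ for the ~1.4 million lipids of a 25 µm² corral) over four events:
kinase arrival, kinase departure, single-lipid phosphorylation,
single-lipid dephosphorylation.  The kinase channel modulates the
phosphorylation propensity by $N_E(t)/\bar N_E$, so composition-level
feedback stays in $k(x)$ while copy-number fluctuations — the
experimentally identified noise source — enter multiplicatively.  An
optional `recruit_coupling` multiplies arrivals by $(1 + c\,x)$ for
product-enhanced recruitment; it defaults to 0 because the composition
rate law `k(x)` already carries the product feedback, and it is
labelled exploratory.
Tau-leaping is deliberately not offered: corral ensembles are exactly
reproducible per-corral via seeds derived from one root seed.

Kinase copy-number defaults are set to the physical scales of the
underlying experiments: mean membrane dwell 2 s (single-molecule dimers
persist 1–2 s) and an on-rate giving ~10 kinases/µm² at 50 nM solution
concentration (the calibrated density scale of the kinetic
measurements).  At these scales a 25 µm² corral holds ~250 copies and
the ensemble mean converges on the deterministic trace (sup-norm < 0.01
over 200 corrals), while a 1 µm² corral holds ~10 copies and shows
strong trajectory variation — the size dependence called stochastic
geometry sensing.

# What the synthetic data do and do not emulate

The generator reproduces: Poisson arrival, exponential(-mixture) dwells,
state-dependent 2D Brownian motion with a two-state monomer/dimer Markov
switch, per-fluorophore maturation (~80%) and exponential bleaching,
Gaussian camera noise, Hill-cooperative titrations, and
composition-dependent reaction traces with explicit kinase copy-number
noise.  It does not emulate: rendered TIRF images or spot
detection/linking (trajectories are consumed as tables), EMCCD noise
physics beyond Gaussian, fluorophore blinking, explicit pairwise
collision dynamics of dimerization, membrane hydrodynamics, or the
spatial morphology of lipid compositional patterns.  Passing tests
therefore validate the estimators against their assumed statistical
structure, not against detection artifacts or spatial pattern formation.

Dimerization as a per-particle Markov switch (rather than explicit pair
encounters) is sufficient because every downstream analysis consumes
only state-dependent dwell and mobility; membrane dimer on/off rates are
not quantified experimentally, so the defaults are illustrative.

The acquisition frame interval of single-particle movies is similarly
unreported; 0.05 s is used as the default because it equals the
published dwell-histogram bin width, and it is a free parameter.

# Problem sizes and numerical tolerances used in validation

Validation studies use: 10⁴–10⁵ dwell or step draws per fit
(survival-fit recovery is unbiased to ~3% and seed-to-seed spread ~5% at
3×10⁴ draws, so summary values are medians over replicate fits, the way
experimental tables pool 3–5 technical replicates); 10⁴–10⁵ brightness
traces; 20-seed recovery panels; 100-replicate order-selection and
root-oracle panels; corral ensembles of 50–200 compartments at 1–25 µm².
Noise-free self-fits are asserted at 0.5–2%, stochastic recoveries at
5–10%, analytic survival comparisons at sup-norm 0.02, and the
calibration round trip at 10⁻¹⁰ relative error.

# Known limitations

* Survival-curve fitting in log space slightly underweights the head of
  the distribution; its small-sample bias (a few percent at 10⁴ draws)
  is characterized in tests rather than corrected.
* The immobile-track threshold (default: maximum excursion below twice
  the localization sigma) and the edge margin (5% of field width) are
  plausible reconstructions of under-specified published filters; both
  are exposed as parameters.
* `half_time()` reports the first crossing of $x = 0.5$; for
  non-monotone stochastic traces this is the first passage, not the
  median occupancy time.
* The corral model exchanges kinase with solution but not lipids with
  neighbouring membrane, matching chromium-barrier experiments only.
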