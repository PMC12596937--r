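---
title: "A mechanistic model of fed-batch in vitro transcription"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mechanistic model of fed-batch in vitro transcription}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivtsim)
```

## The system

In vitro transcription (IVT) polymerizes nucleoside triphosphates (NTPs)
into RNA on a DNA template using T7 RNA polymerase. Run as a fed-batch —
with bolus additions of NTPs, Mg and base — the reaction reuses the
expensive catalysts (polymerase, template, and, for capped mRNA, the AG cap
analog) to polymerize far more substrate than a batch can hold. But
fed-batch operation drives the broth into regimes batch reactions never
see: counterions accumulate with every feed, the pH falls by more than a
unit as polymerization releases protons, and the phosphate liberated by
pyrophosphatase can push the solution past the solubility limit of
magnesium phosphate. `ivtsim` implements a mechanistic model of all of
this: differential equations for the enzymatic kinetics coupled at every
instant to the nonlinear algebraic equations of ionic speciation.

## Speciation: the algebraic core

The reactor state is a vector of *conserved totals* (per moiety: Mg, each
NTP, orthophosphate, pyrophosphate, tris, acetate, the cap analog, plus
the spectators sodium, chloride, strong-base equivalents and RNA backbone
charges). At each instant these totals are distributed over ~30 aqueous
species (free ions, protonated forms, Mg complexes) by solving
mass-action + mass-balance + electroneutrality equations. Formation
constants are 25 °C infinite-dilution values from critically evaluated
stability-constant compilations (ATP protonation pK 6.5 and 4.0, Mg·ATP
log K 4.29, phosphate pK 12.375/7.198/2.148, Mg·HPO4 2.87, tris pK 8.07,
acetate pK 4.756, pyrophosphate pK 9.4, pKw 13.997). The temperature field
is carried but no van 't Hoff correction is applied — a documented
limitation, as is the ideal-solution assumption (activities =
concentrations; a Davies-type correction would slot in where species
concentrations enter the mass-action laws).

Numerically the solver works on the logarithms of the free component
concentrations — the species span more than ten orders of magnitude — with
a damped Newton iteration and an analytic Jacobian, warm-started along ODE
trajectories. If Newton fails, a guaranteed fallback runs nested bisection:
the charge balance is strictly monotone in [H+], the Mg balance strictly
monotone in [Mg2+], and every ligand's free concentration then has a closed
form (each default-tableau species carries at most one ligand and one Mg).
Converged states satisfy per-moiety mass balance and electroneutrality to
better than 1e-8 relative (the test suite checks 200 randomized
compositions).

Three derived quantities feed the kinetics:

* **pH** from the free proton concentration.
* **Effective salt** $[salt] = \sum_i \omega_i \,[\mathrm{ion}_i]$, a
  weighted sum over all charged complexes. The shipped weights are a
  synthetic calibration chosen once to reproduce the orderings that
  characterize IVT salt inhibition — chloride-bearing salts substantially
  more disruptive than acetate at equal molarity, free Mg²⁺ strongly
  disruptive per mole ($\omega_{Cl}=1.5$, $\omega_{Na}=0.5$,
  $\omega_{Ac}=0.25$, $\omega_{Mg^{2+}}=3$, complexed/protonated forms
  intermediate). They are exposed in the constants file and should be
  replaced with system-specific estimates where available.
* **Supersaturation** of anhydrous magnesium phosphate,
  $\sigma = \ln\!\big([\mathrm{Mg^{2+}}]^3[\mathrm{PO_4^{3-}}]^2 /
  K_{sp}\big)$, with $K_{sp} = 10^{-24}$ (a standard tabulated value for
  Mg₃(PO₄)₂ at 25 °C). $\sigma > 0$ means a thermodynamic driving force
  for precipitation; only the driving force is modeled, not nucleation or
  growth kinetics. When either free ion is absent, σ is reported as −Inf.

## Kinetics: a lumped elongation-limited rate law

The transcription rate is

$$r = k_{cat}\,[\mathrm{DNA}]\;\phi_{occ}\;\Gamma_{pH}\;
  \prod_{i \in \{A,U,C,G\}} \frac{[\mathrm{Mg{\cdot}NTP}_i]}
  {K_M + [\mathrm{Mg{\cdot}NTP}_i]}$$

* $\phi_{occ}$ is the equilibrium promoter occupancy from the exact
  two-species binding quadratic with $K_d = k_{off}/k_{on}$ and
  $k_{off} = k_{off,1M}\,[salt]^{n_{salt}}$. The detachment scale is
  $10^{3.93}\,s^{-1}$ for the salt-sensitive reference construct and
  $10^{2.93}$ for ordinary sequences. The exponent defaults to
  $n_{salt} = 5$, representative of counterion-release stoichiometries
  measured for polymerase–promoter interactions.
* $\Gamma_{pH} = (1 + [H^+]/K_a + K_b/[H^+])^{-1}$ is the classical
  diprotic enzyme pH response; the defaults $K_a = 10^{-7}$,
  $K_b = 10^{-9}$ put its maximum at pH 8, the usual IVT operating point.
* The saturation term multiplies Michaelis factors in the free Mg·NTP
  complex concentrations with a shared $K_M$ (0.15 mM); the four NTPs are
  not separately identifiable from rate data alone.
* $k_{cat} = 0.017\,s^{-1}$ per occupied promoter is the whole-transcript
  completion rate, equivalent to ~75 nt/s elongation over the bundled
  4.4-knt construct — inside the measured T7 elongation range and sized so
  that the reference optimized protocol reaches the ~10 g/L scale in a
  3-hour process.

This is a deliberately lumped law: binding, initiation and elongation are
not resolved as separate states. The module boundary (`transcription_rate`)
isolates the functional form so a finer-grained kinetic chain can replace
it without touching speciation, the reactor, or the optimizer.

Polymerase deactivation is not modeled (relevant only for residence times
well beyond the 2–3 h horizon simulated here), and neither are abortive
initiation, dsRNA byproducts, or runoff-length heterogeneity.

## Proton bookkeeping

Rather than imposing a fixed proton-release stoichiometry, the reactor
does exact charge accounting. Polymerizing one NTP converts an NTP moiety
(basis charge −4) into one backbone phosphodiester charge (−1, a spectator)
plus — after instantaneous pyrophosphatase action, PPi → 2 Pi — two
orthophosphate moieties. Electroneutrality then forces the buffers to
re-protonate, and the pH falls. At pH ≈ 8 this releases almost exactly one
proton equivalent per NTP incorporated, so the textbook "one proton per
NTP" emerges from the chemistry instead of being a tunable input. Capped
initiation consumes one cap analog in place of the first ATP and GTP; its
four phosphates stay on the RNA. Elemental phosphorus closes exactly by
construction, and the tests verify it to 1e-8 along whole trajectories.

## The reactor

`simulate_ivt()` integrates the coupled system with `deSolve::lsoda`
(relative tolerance 1e-8, per-state absolute floors resolving sub-nM RNA),
stopping exactly at every bolus time: no interpolation across
discontinuities. A bolus mixes instantaneously and isothermally,
$c \leftarrow (cV + c_f V_f)/(V + V_f)$, and both the pre- and post-event
states appear in the output (the reporting grid is the union of a uniform
60 s grid and all event times). Continuous feeding is supported as a
piecewise-constant rate profile; the tests confirm that finely discretized
boluses converge to the continuous solution. RNA *amount* is monotone
non-decreasing; the reported concentration dips at boluses by dilution.

`decompose_rate_decline()` factors $r(t)/r(0)$ exactly into catalyst
dilution, salt-driven occupancy loss, pH, and NTP saturation terms — the
diagnostic that attributes a fed-batch rate collapse to its mechanism.

## Co-transcriptional capping

With transcripts initiating A-then-G, the AG cap analog competes with
sequential ATP+GTP addition at initiation. The quasi-steady-state result
is the instantaneous cap fraction

$$CF_i = \frac{[cap]}{[cap] + \lambda\,[\mathrm{ATP}][\mathrm{GTP}]/
  (1 + [\mathrm{GTP}]/\theta)}$$

identifiable only through the composites λ (M⁻¹) and θ (a GTP half-effect
concentration). The denominator is implemented as $1 + [\mathrm{GTP}]/\theta$:
θ carries concentration units, which makes the competition term carry the
units of a concentration as it must. The cumulative CF integrates
$d(\mathrm{capped})/dt = CF_i\,r$ inside the same ODE as the reactor state
(no separate quadrature), and cap-analog consumption equals capped RNA
exactly. The cap analog contributes to the effective salt with the same
default weight as a free NTP; this is configurable.

Default (λ, θ) are obtained by inverting the two-condition calibration
layout — solving $CF_i(3.6, 7, 0.3\,\mathrm{mM}) = 0.48$ and
$CF_i(2, 0.25, 0.05\,\mathrm{mM}) = 0.50$ for the two unknowns — giving
λ ≈ 133 M⁻¹, θ ≈ 0.75 mM. Whether such tabulated calibration predictions
were computed instantaneously at t = 0 or by full batch integration is
ambiguous; both modes are implemented (`predict_cf_batch()`), the
integrated predictions sit systematically above the instantaneous ones as
NTPs deplete, and the discrepancy is reported in the test suite. Fitting
uses full batch integration by default.

## Calibration and design

`mle_fit_capping()` maximizes an independent-Gaussian likelihood with
per-measurement standard deviations, in log-parameter space (estimates are
positive by construction); the covariance is the inverse observed
information mapped back by the delta method. Truncation of the Gaussian to
[0, 1] is ignored in the likelihood — an approximation that is benign at
the 0.05–0.10 standard deviations typical of CF measurements. A key
computational device: the concentration/rate trajectory of a calibration
batch is insensitive to (λ, θ) themselves (cap consumption is µM-scale
against a mM-scale inventory), so one simulation per condition is reused
for every parameter value during fitting and Monte Carlo propagation.
Prediction intervals sample (λ, θ) from the fitted covariance, rejecting
non-positive draws, and are deterministic given a seed.

`fisher_information()` sums gradient outer products of the predicted CF
(closed-form gradients in instantaneous mode, central differences in
integrated mode), and `d_optimal_design()` maximizes its determinant over
initial (ATP, GTP, cap) boxes by seeded Latin-hypercube search with a
Nelder–Mead polish. The design module defaults to instantaneous-mode
information — the integrated mode costs one simulation per candidate
experiment and is available where that fidelity matters. With two
experiments the optimal design splits the GTP levels to the two bounds, as
intuition about identifying a saturation constant suggests.

## Policy optimization

The feeding policy is scored by

$$J(F) = \nu_{NTP} \sum_{N}\sum_{t_i \in t_N}
  ([NTP]_{F,t_i} - [NTP]_{sp})^2
  + \nu_{pH} \sum_{t_i \in t_{pH}} (pH_{F,t_i} - pH_{sp})^2
  - \nu_{RNA}\,[RNA]_{t_f}$$

with NTP in mM, pH in pH units and RNA in µM, so the default unit weights
put the terms on comparable scales for the reference scenarios; the
evaluation grids default to 5-minute spacing. The decision vector fixes
event times on a uniform grid and optimizes amounts only (initial Mg, tris
and NTP levels plus per-event NTP/Mg/NaOH feed concentrations), keeping
the search box-bounded; time optimization is a documented extension. The
search is a seeded Latin-hypercube exploration followed by a Nelder–Mead
polish — the objective is nonsmooth at event times, so derivative-free
methods are the right default — and failed simulations return a large
finite penalty rather than an exception. `low_ph_variant()` converts an
objective to the anti-precipitation strategy: pH tracking moves to a tail
window (t ≥ 0.9 t_f) at setpoint 7.3 and the Mg feed bounds shrink
slightly.

## Reference scenarios

`make_scenarios()` builds five deterministic protocols — all synthetic
reconstructions designed against this model, not transcriptions of any
laboratory recipe:

* **batch_capping** — 2 mM of each NTP + 2 mM cap analog, pH 8 tris
  buffer.
* **heuristic_fedbatch** — 5 mM NTP initial condition, tris-HCl buffer
  (60 mM tris / 45 mM chloride), Mg co-fed 1:1 as MgCl₂, and identical
  feeds sized once from the *initial* reaction rate. On the salt-sensitive
  construct this protocol's effective salt climbs steeply and its rate
  collapses below 10% of initial near 2.7 µM RNA — the characteristic
  failure of feeding on initial kinetics.
* **optimized_fedbatch_highpH / _lowpH** — 2 mM setpoints, a minimal tris
  base buffer, magnesium acetate co-feeds (1.0 and 0.85 Mg per NTP), and
  adaptive boluses that restore setpoints and titrate pH to target
  (8.0 throughout, or relaxing to 7.3 at the end of the process). These
  are built by `design_feed_schedule()`, which steps the model between
  events — the fixed point a setpoint-tracking optimizer converges to.
* **continuous_feed_literature_like** — piecewise-constant continuous
  feeding of an ordinary (10^2.93) construct.

The bundled construct is 4,400 nt (A 1210 / U 897 / C 900 / G 1393),
molar mass ≈ 1.43 MDa, so 7 µM corresponds to 10 g/L. The sizes simulated
here — millilitre volumes, nine boluses over three hours — were chosen as
representative bench scale; all are configurable.

What passing tests on these scenarios do and do not show: the generators
emulate deterministic reactor physics with idealized instantaneous mixing,
exact measurement-free feeding, and noise models (Gaussian CF error,
lognormal concentration error) that are stationary and independent. They
cannot stand in for real chromatographic measurement bias, enzyme lot
variability, or actual precipitation dynamics — σ here is a driving force,
and the model deliberately contains no precipitation sink.

## Numerical choices and degenerate inputs

* Speciation tolerance 1e-10 scaled (1e-8 enforced); Newton step capped at
  3 e-folds with backtracking line search; bisection fallback is
  guaranteed for the shipped tableau.
* Integrator: lsoda, rtol 1e-8; halving tolerances moves final RNA by
  < 0.1%.
* Zero totals drop out of the unknown set (free concentration exactly 0).
* CF with neither cap nor an ATP·GTP pathway is defined as 0 with a
  warning; zero-RNA trajectories report CF as missing.
* k_off(0) = 0: the irreversible-binding limit is allowed.
* Optimizer candidates are projected onto the box before evaluation, so
  Nelder–Mead never leaves the feasible region.

## Limitations

Ionic-strength-dependent equilibrium constants, temperature corrections,
crystallization kinetics, CSTR outflow, dsRNA and abortive byproducts, and
measurement-delay feedback control are all out of scope. The effective-salt
weights and the salt exponent are calibration stand-ins pending
system-specific measurements; every number lives in one versioned constants
object (`ivt_constants()`) precisely so they can be replaced wholesale.
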