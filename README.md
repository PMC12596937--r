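# ivtsim

Mechanistic simulation and optimization of **fed-batch in vitro
transcription (IVT)** for RNA synthesis.

IVT — cell-free polymerization of NTPs into RNA by T7 RNA polymerase on a
DNA template — is the workhorse reaction behind mRNA vaccines and
therapeutics. Fed-batch operation reuses the expensive catalysts
(polymerase, template, cap analog) across repeated NTP feeds, but brings
failure modes batch reactions never meet: counterion accumulation that
detaches polymerase from the promoter, a falling pH as polymerization
releases protons, and magnesium phosphate supersaturation once
pyrophosphatase converts the released PPi to orthophosphate. `ivtsim` is
for process engineers and modelers who want to simulate, diagnose, and
optimize these dynamics before going to the bench.

## The model

A stiff ODE system for the conserved reactor totals is coupled, at every
instant, to the nonlinear algebraic equations of ionic speciation
(mass action + mass balance + electroneutrality over ~30 species). The
speciation state feeds the transcription rate law

    r = k_cat [DNA] * phi_occ * Gamma_pH * prod_i [MgNTP_i]/(K_M + [MgNTP_i])

with promoter occupancy `phi_occ` set by the salt-dependent detachment
constant `k_off = k_off_1M * [salt]^n_salt`, where the effective salt
`[salt] = sum_i omega_i [ion_i]` weighs every ionic complex by its
disruptiveness, and `Gamma_pH = (1 + [H+]/K_a + K_b/[H+])^-1` is the
classical diprotic pH response. Precipitation risk is tracked as the
supersaturation `sigma = ln([Mg2+]^3 [PO4^3-]^2 / Ksp)` of magnesium
phosphate. Co-transcriptional capping enters as initiation competition
between the AG cap analog and ATP+GTP:

    CFi = [cap] / ([cap] + lambda [ATP][GTP] / (1 + [GTP]/theta))

with the identifiable composites `lambda` and `theta` calibrated by
maximum likelihood from batch cap-fraction measurements, designed by a
D-optimal criterion.

On top of the simulator sit model-based tools: setpoint-tracking
feed-policy optimization (quadratic NTP and pH tracking minus an RNA
reward), a low-pH anti-precipitation variant, D-optimal design of capping
calibration experiments, MLE with Monte Carlo prediction intervals, and a
generator of reference scenarios (a salt-sensitive heuristic-vs-optimized
fed-batch pair, a capped batch, and a continuous-feed protocol).

## Worked example

Speciate a working mix, simulate the bundled optimized fed-batch protocol,
and calibrate the capping model:

```r
library(ivtsim)

mix <- adjust_to_pH(
  ivt_solution(mg = 10, atp = 2, utp = 2, ctp = 2, gtp = 2, cap = 2,
               tris = 40, sodium = 24, na_counterions = FALSE), 8.0)
solve_speciation(mix)
#> <ivt_speciation>
#>   pH 8  effective salt 84.69 mM  sigma -Inf
#>   residual 2.064668e-11 in 8 iterations

sim <- simulate_scenario("optimized_fedbatch_highpH", make_scenarios())
sim
#> <ivt_simulation> 190 states over 180 min
#>   final RNA 9.166 uM (13.09 g/L); final CF 0.954; final pH 7.87
#>   final effective salt 167.2 mM; peak sigma 8.903
```

The printout reads: after 3 h of model-designed feeding the reactor holds
9.2 µM RNA (13.1 g/L) with 95% of transcripts capped; the pH was held near
8, the effective salt climbed to 167 mM, and the Mg3(PO4)2 supersaturation
peaked at sigma = 8.9 (a positive driving force — the low-pH scenario
variant exists to shrink it). `autoplot(sim)` draws the trajectories and
`decompose_rate_decline(sim)` attributes any rate loss to salt, catalyst
dilution, pH, or NTP saturation.

```r
fit <- mle_fit_capping(capping_calibration_data())
tidy(fit)
#> # A tibble: 2 x 5
#>   term     estimate std.error conf.low conf.high
#>   <chr>       <dbl>     <dbl>    <dbl>     <dbl>
#> 1 lambda       45.1      17.8     10.2      80.0
#> 2 theta_mM     10.6      18.7    -26.0      47.3
```

Two designed batch conditions identify the capping composites: the
competition coefficient lambda ≈ 45 M⁻¹ and the GTP half-effect
theta ≈ 10.6 mM (wide intervals are expected from a two-point exactly
identified design; `d_optimal_design()` chooses such conditions, and
`cf_prediction_interval()` propagates the covariance to CF predictions).

A thin command-line wrapper (`inst/cli/ivtsim`) exposes `speciate`,
`simulate`, `optimize`, `fit-capping`, `design-experiments` and
`make-fixtures` over YAML/CSV files.

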