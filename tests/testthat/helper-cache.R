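# Shared, lazily computed fixtures: the scenario bundle and its simulations
# are expensive relative to individual assertions, so they are built once
# per test run and reused across files.

.ivt_test_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.ivt_test_cache[[name]]))
    assign(name, force(expr), envir = .ivt_test_cache)
  .ivt_test_cache[[name]]
}

scenario_bundle <- function() cached("bundle", make_scenarios())

sim_scenario_cached <- function(nm)
  cached(paste0("sim_", nm), simulate_scenario(nm, scenario_bundle()))

mle_fit_cached <- function()
  cached("mle_integrated",
         mle_fit_capping(capping_calibration_data(), mode = "integrated"))

# amount (mol) of a trajectory column given in mM
amount_mol <- function(tr, col) tr[[col]] / 1000 * tr$volume_L

# total phosphorus amount (mol) along a trajectory: 3 per NTP, 4 per cap
# analog, 1 per orthophosphate, 2 per pyrophosphate, 1 per backbone charge
phosphorus_amount <- function(tr) {
  3 * (amount_mol(tr, "atp_mM") + amount_mol(tr, "utp_mM") +
         amount_mol(tr, "ctp_mM") + amount_mol(tr, "gtp_mM")) +
    4 * amount_mol(tr, "cap_mM") +
    amount_mol(tr, "phosphate_mM") + 2 * amount_mol(tr, "pyrophosphate_mM") +
    amount_mol(tr, "rna_backbone_mM")
}

# rows not immediately following a bolus (volume unchanged vs previous row)
segment_rows <- function(tr) c(TRUE, diff(tr$volume_L) < 1e-15)
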