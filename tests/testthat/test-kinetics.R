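# Rate law components: salt power law, pH bell factor, promoter binding,
# NTP saturation, and the stoichiometric structure of the reaction ODE.

test_that("promoter detachment follows the salt power law", {
  p <- ivt_kinetics(k_off_1M = 10^2.93, n_salt = 5)
  expect_equal(k_off(1, p), p$k_off_1M)
  expect_equal(k_off(0, p), 0)
  salts <- c(0.05, 0.1, 0.2, 0.4)
  expect_equal(k_off(salts / 2, p), k_off(salts, p) / 2^p$n_salt)
  expect_true(all(diff(k_off(salts, p)) > 0))
})

test_that("the pH factor is a bell in (0,1] peaking at sqrt(Ka*Kb)", {
  p <- ivt_kinetics(K_a = 1e-7, K_b = 1e-9)
  expect_equal(gamma_pH(8, p), 1 / (1 + 0.1 + 0.1))  # = 0.8333...
  # K_a -> Inf, K_b -> 0 limit: factor ~ 1 at any pH
  p1 <- ivt_kinetics(K_a = 1e6, K_b = 1e-30)
  expect_equal(gamma_pH(c(2, 7, 12), p1), rep(1, 3), tolerance = 1e-5)
  # interior maximum at [H+] = sqrt(Ka Kb), i.e. pH 8 here
  grid <- seq(2, 13, by = 0.001)
  g <- gamma_pH(grid, p)
  expect_equal(grid[which.max(g)], -log10(sqrt(p$K_a * p$K_b)),
               tolerance = 1e-2)
  expect_true(all(g > 0 & g <= 1))
  # single interior maximum: increasing then decreasing
  dg <- diff(g)
  expect_equal(sum(diff(sign(dg)) != 0), 1)
})

test_that("promoter occupancy matches the Langmuir closed form and its limits", {
  p <- ivt_kinetics()
  cat_big <- ivt_catalysts(dna_nM = 50, polymerase_nM = 200)
  expect_equal(promoter_occupancy(cat_big, 0, p), 1)
  expect_equal(promoter_occupancy(ivt_catalysts(50, 0), 10, p), 0)
  expect_equal(promoter_occupancy(ivt_catalysts(0, 100), 10, p), 0)
  # vanishing DNA: free polymerase ~ total, occupancy -> P/(P + Kd);
  # at P = Kd this is 1/2
  Kd <- 2e-7
  cat_l <- ivt_catalysts(dna_nM = 1e-3, polymerase_nM = Kd * 1e9)
  expect_equal(promoter_occupancy(cat_l, Kd * p$k_on, p), 0.5,
               tolerance = 1e-4)
  # occupancy decreases with k_off
  occ <- vapply(c(0.1, 1, 5, 20), function(ko)
    promoter_occupancy(cat_big, ko, p), numeric(1))
  expect_true(all(diff(occ) < 0))
})

test_that("transcription rate vanishes without NTPs, scales with DNA, and is salt-inhibited at high Mg", {
  cc <- ivt_constants()
  p <- ivt_kinetics()
  cats <- ivt_catalysts()
  spec_of <- function(...) solve_speciation(ivt_solution(...), cc)
  # one NTP absent -> no complete transcripts
  r0 <- transcription_rate(spec_of(mg = 10, atp = 2, utp = 2, ctp = 2,
                                   tris = 40), cats, p)
  expect_equal(r0, 0)
  # linear in DNA
  s <- spec_of(mg = 10, atp = 2, utp = 2, ctp = 2, gtp = 2, tris = 40)
  r1 <- transcription_rate(s, ivt_catalysts(100, 500), p)
  r2 <- transcription_rate(s, ivt_catalysts(200, 500), p)
  expect_equal(r2 / r1, 2, tolerance = 1e-6)
  # large Mg excess depresses the rate despite full Mg.NTP complexation
  # (free Mg inflates the effective salt and with it promoter detachment)
  r_bal <- transcription_rate(spec_of(mg = 10, atp = 2, utp = 2, ctp = 2,
                                      gtp = 2, tris = 40), cats, p)
  r_high <- transcription_rate(spec_of(mg = 60, atp = 2, utp = 2, ctp = 2,
                                       gtp = 2, tris = 40), cats, p)
  expect_lt(r_high, 0.5 * r_bal)
})

test_that("rate is non-increasing in effective salt at fixed composition", {
  cc <- ivt_constants()
  p <- ivt_kinetics(k_off_1M = 10^3.93)
  cats <- ivt_catalysts()
  rates <- vapply(c(0, 25, 50, 100, 200), function(nacl)
    transcription_rate(solve_speciation(
      ivt_solution(mg = 10, atp = 2, utp = 2, ctp = 2, gtp = 2, tris = 40,
                   sodium = nacl, chloride = nacl), cc), cats, p),
    numeric(1))
  expect_true(all(diff(rates) < 0))
})

test_that("sodium chloride depresses the rate at least as much as sodium acetate", {
  cc <- ivt_constants()
  p <- ivt_kinetics(k_off_1M = 10^3.93)   # salt-sensitive construct
  cats <- ivt_catalysts()
  # pH-8 working mix (so the comparison isolates the salt effect, not the
  # alkalinity of the added sodium salt)
  rate_with <- function(nacl = 0, naac = 0) {
    sol <- adjust_to_pH(ivt_solution(
      mg = 10, atp = 2, utp = 2, ctp = 2, gtp = 2, tris = 40,
      sodium = 16 + nacl + naac, chloride = nacl, acetate = naac,
      na_counterions = FALSE), 8.0, cc)
    transcription_rate(solve_speciation(sol, cc), cats, p)
  }
  for (x in c(10, 25, 50, 100, 150, 200))
    expect_lte(rate_with(nacl = x), rate_with(naac = x) * (1 + 1e-9))
  # and the effect is material at high additions
  expect_lt(rate_with(nacl = 200), 0.8 * rate_with(naac = 200))
})

test_that("a batch integrates to the stoichiometric completion of the limiting NTP", {
  # GTP limiting by a wide margin; long horizon, fast catalysis
  sq <- ivt_sequence_default()
  init <- adjust_to_pH(ivt_solution(atp = 4, utp = 4, ctp = 4, gtp = 1,
                                    mg = 14, tris = 40,
                                    sodium = 26, na_counterions = FALSE),
                       8.0)
  pol <- feed_policy(init, ivt_catalysts(300, 500), t_final = 4 * 3600)
  sim <- simulate_ivt(pol, ivt_kinetics(k_off_1M = 10^2.93))
  rna_max <- 1e-3 / sq$counts[["G"]]   # limiting-NTP oracle (M)
  final <- tail(sim$trajectory$rna_uM, 1) * 1e-6
  expect_equal(final, rna_max, tolerance = 0.02)
  # the limiting NTP is the one driven to exhaustion first
  expect_lt(tail(sim$trajectory$gtp_mM, 1), 0.02)
  expect_gt(tail(sim$trajectory$atp_mM, 1), 1)
})

test_that("elemental phosphorus and per-base balances close along trajectories", {
  sim <- sim_scenario_cached("heuristic_fedbatch")
  tr <- sim$trajectory
  keep <- segment_rows(tr)
  # phosphorus: within integration segments the total P amount is constant
  P <- phosphorus_amount(tr)
  seg <- split(P, cumsum(!keep))
  for (s in seg) if (length(s) > 1)
    expect_lt(max(abs(s - s[1])) / s[1], 1e-7)
  # per-base balance on the batch scenario (no feeds, capped transcripts):
  # NTP_i + n_i RNA - capped (for A and G) is constant
  simb <- sim_scenario_cached("batch_capping")
  trb <- simb$trajectory
  sq <- scenario_bundle()$seq
  for (base in c("atp", "utp", "ctp", "gtp")) {
    n_i <- sq$counts[[c(atp = "A", utp = "U", ctp = "C", gtp = "G")[base]]]
    bal <- amount_mol(trb, paste0(base, "_mM")) +
      n_i * trb$rna_uM * 1e-6 * trb$volume_L -
      (if (base %in% c("atp", "gtp")) trb$capped_uM * 1e-6 * trb$volume_L else 0)
    expect_lt(max(abs(bal - bal[1])) / bal[1], 1e-7)
  }
})

test_that("fed-batch rate decline decomposes into salt, catalyst, pH and NTP factors", {
  sim <- sim_scenario_cached("heuristic_fedbatch")
  tr <- sim$trajectory
  # the instantaneous rate at the (fixed) NTP-setpoint-or-above state
  # declines over the run
  expect_lt(tail(tr$rate_Ms, 1), 0.1 * tr$rate_Ms[1])
  d <- decompose_rate_decline(sim)
  expect_lt(max(abs(d$product - d$rate_ratio)), 1e-6)
  # at the first time the rate drops below 10% of initial, salt is the
  # dominant (smallest) factor for this chloride-heavy protocol
  i <- which(d$rate_ratio < 0.1)[1]
  fs <- unlist(d[i, c("f_catalyst", "f_salt", "f_ph", "f_ntp")])
  expect_identical(names(which.min(fs)), "f_salt")
})
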