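# Speciation equilibria: oracles (closed forms solved independently in the
# tests), conservation properties, and the derived quantities (effective
# salt, supersaturation).

test_that("pure water is neutral and a lone buffer matches the exact one-site closed form", {
  cc <- ivt_constants(list(Kw = 14))
  res <- solve_speciation(ivt_solution(), cc)
  expect_equal(res$pH, 7, tolerance = 1e-6)

  # tris base + tris.HCl at several ratios; oracle: exact scalar proton
  # condition for a single monoprotic buffer, solved by uniroot here
  cc <- ivt_constants()
  Ka10 <- unname(cc$logK["trisH+"])   # log10 association constant
  Kw <- 10^unname(cc$logK["OH-"])
  for (cl_mM in c(5, 10, 20, 35)) {
    total <- 40e-3; cl <- cl_mM / 1000
    oracle <- stats::uniroot(function(h) {
      trisH <- total / (1 + 1 / (10^Ka10 * h))
      trisH + h - Kw / h - cl          # charge balance
    }, c(1e-14, 1e-1), tol = 1e-18)$root
    res <- solve_speciation(ivt_solution(tris = 40, chloride = cl_mM), cc)
    expect_equal(res$pH, -log10(oracle), tolerance = 1e-6)
  }
  # and the textbook buffer-ratio form away from the water limits
  res <- solve_speciation(ivt_solution(tris = 40, chloride = 20), cc)
  expect_equal(res$pH, Ka10 + log10((40 - 20) / 20), tolerance = 1e-3)
})

test_that("Mg-NTP binding with protonation suppressed matches the quadratic oracle", {
  off <- c("HATP3-" = -99, "H2ATP2-" = -99, "MgHATP-" = -99)
  cc <- ivt_constants(list(logK = off))
  K <- 10^unname(cc$logK["MgATP2-"])
  Tm <- 5e-3; Ta <- 5e-3
  # equal totals: free Mg solves K m^2 + m - T = 0
  m_oracle <- (-1 + sqrt(1 + 4 * K * Tm)) / (2 * K)
  res <- solve_speciation(ivt_solution(mg = 1000 * Tm, atp = 1000 * Ta), cc)
  expect_equal(unname(res$species["Mg2+"]), m_oracle, tolerance = 1e-6)
  # bound + free account for all Mg
  expect_equal(unname(res$species["Mg2+"] + res$species["MgATP2-"]), Tm,
               tolerance = 1e-9)
})

test_that("mass and charge balances close to 1e-8 over randomized compositions", {
  cc <- ivt_constants()
  tab <- ivtsim:::prep_tableau(cc)
  set.seed(42)
  n_bad <- 0
  for (i in 1:200) {
    sol <- ivt_solution(
      mg = runif(1, 0, 40), atp = runif(1, 0, 8), utp = runif(1, 0, 8),
      ctp = runif(1, 0, 8), gtp = runif(1, 0, 8), cap = runif(1, 0, 3),
      phosphate = runif(1, 0, 60), pyrophosphate = runif(1, 0, 2),
      tris = runif(1, 0, 60), acetate = runif(1, 0, 40),
      chloride = runif(1, 0, 50), strong_base = runif(1, 0, 20),
      rna_backbone = runif(1, 0, 40),
      na_counterions = sample(c(TRUE, FALSE), 1))
    res <- solve_speciation(sol, cc)
    # recompute per-moiety sums from the species table, independently
    tot <- ivtsim:::solution_totals(sol)
    tc <- ivtsim:::totals_to_components(tot)
    A <- cc$stoich[names(res$species), , drop = FALSE]
    for (compo in setdiff(colnames(A), "H")) {
      Tj <- tc$T[[compo]]
      if (Tj > 0) {
        got <- sum(A[, compo] * res$species)
        if (abs(got - Tj) > 1e-8 * Tj) n_bad <- n_bad + 1
      }
    }
    Q <- sum(cc$charge[names(res$species)] * res$species) + tc$fixed_charge
    S <- sum(abs(cc$charge[names(res$species)]) * res$species) + tc$fixed_abs
    if (abs(Q) > 1e-8 * S) n_bad <- n_bad + 1
  }
  expect_identical(n_bad, 0)
})

test_that("strong acid lowers pH and strong base raises it, monotonically", {
  cc <- ivt_constants()
  base <- function(cl, sb) solve_speciation(
    ivt_solution(mg = 10, atp = 3, gtp = 3, tris = 30, phosphate = 5,
                 chloride = cl, strong_base = sb), cc)$pH
  ph_acid <- vapply(c(0, 5, 10, 20, 40), function(cl) base(cl, 0), numeric(1))
  expect_true(all(diff(ph_acid) < 0))
  ph_base <- vapply(c(0, 5, 10, 20, 40), function(sb) base(0, sb), numeric(1))
  expect_true(all(diff(ph_base) > 0))
})

test_that("effective salt is the omega-weighted sum over complexes", {
  cc <- ivt_constants()
  res <- solve_speciation(ivt_solution(tris = 40, chloride = 20, mg = 5), cc)
  # null weights
  cc0 <- cc; cc0$omega[] <- 0; cc0$omega_spectator[] <- 0
  expect_equal(effective_salt(res, cc0), 0)
  # single complex identity: weight only trisH+
  cc1 <- cc0; cc1$omega["trisH+"] <- 1
  expect_equal(effective_salt(res, cc1), unname(res$species["trisH+"]))
  # linearity of the sum
  cc2 <- cc0; cc2$omega["trisH+"] <- 1; cc2$omega["Mg2+"] <- 0.5
  expect_equal(effective_salt(res, cc2),
               unname(res$species["trisH+"] + 0.5 * res$species["Mg2+"]))
  # missing weight is a configuration error
  ccNA <- cc; ccNA$omega["Mg2+"] <- NA
  expect_error(effective_salt(res, ccNA), "omega")
})

test_that("supersaturation obeys its logarithmic identities", {
  cc <- ivt_constants()
  res <- solve_speciation(
    ivt_solution(mg = 20, phosphate = 30, tris = 30, strong_base = 20), cc)
  m <- unname(res$species["Mg2+"]); p <- unname(res$species["PO43-"])
  ip <- m^3 * p^2
  cc_eq <- cc; cc_eq$Ksp_Mg3PO42 <- ip
  expect_equal(supersaturation(res, cc_eq), 0, tolerance = 1e-12)
  cc10 <- cc; cc10$Ksp_Mg3PO42 <- ip / 10
  expect_equal(supersaturation(res, cc10), log(10), tolerance = 1e-12)
  # doubling free Mg at fixed phosphate adds 3 ln 2
  res2 <- res; res2$species["Mg2+"] <- 2 * m
  expect_equal(supersaturation(res2, cc) - supersaturation(res, cc),
               3 * log(2), tolerance = 1e-12)
  # absent ions: -Inf sentinel; bad Ksp: configuration error
  expect_identical(supersaturation(solve_speciation(ivt_solution(tris = 10), cc), cc),
                   -Inf)
  cc_bad <- cc; cc_bad$Ksp_Mg3PO42 <- -1
  expect_error(supersaturation(res, cc_bad), "Ksp")
})

test_that("acidification at fixed Mg and phosphate totals lowers sigma", {
  cc <- ivt_constants()
  sigmas <- vapply(c(0, 10, 25, 45), function(cl)
    supersaturation(solve_speciation(
      ivt_solution(mg = 15, phosphate = 25, tris = 40, strong_base = 15,
                   chloride = cl), cc), cc), numeric(1))
  # more strong acid -> lower pH -> protonated phosphate -> lower sigma
  expect_true(all(diff(sigmas) < 0))
  # sigma increases with total Mg below saturation of the complexes
  sig_mg <- vapply(c(5, 10, 20, 35), function(mg)
    supersaturation(solve_speciation(
      ivt_solution(mg = mg, phosphate = 25, tris = 40, strong_base = 15),
      cc), cc), numeric(1))
  expect_true(all(diff(sig_mg) > 0))
})

test_that("invalid inputs are rejected cleanly", {
  expect_error(ivt_solution(mg = -1), "negative")
  cc <- ivt_constants()
  expect_error(ivt_constants(list(omega = c(nonexistent = 1))), "unknown")
  expect_error(ivt_constants(list(bogus_field = 1)), "unknown override")
})

test_that("speciation results carry diagnostics and tidy to a species table", {
  res <- solve_speciation(ivt_solution(mg = 10, atp = 2, tris = 30))
  expect_lte(res$residual, 1e-8)
  td <- tidy(res)
  expect_true(all(c("species", "concentration_M") %in% names(td)))
  expect_true(all(td$concentration_M >= 0))
})
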