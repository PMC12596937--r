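# Capping competition model: instantaneous CF closed form, trajectory
# integration against quadrature oracles, and Monte Carlo intervals.

test_that("instantaneous cap fraction has the right limits and monotonicity", {
  p <- ivt_capping(lambda = 100, theta_mM = 1)
  expect_equal(cap_fraction_instant(2e-3, 2e-3, 0, p), 0)
  expect_equal(cap_fraction_instant(0, 2e-3, 1e-3, p), 1)
  expect_warning(out <- cap_fraction_instant(0, 0, 0, p), "no transcription")
  expect_equal(out, 0)
  caps <- 10^seq(-6, 0, by = 0.5)
  cf <- cap_fraction_instant(2e-3, 2e-3, caps, p)
  expect_true(all(diff(cf) > 0))
  expect_true(all(cf >= 0 & cf <= 1))
  expect_gt(tail(cf, 1), 0.999)          # cap -> infinity limit
  expect_lt(cf[1], 0.01)                 # cap -> 0 limit
  atps <- c(0.5, 1, 2, 4, 8) * 1e-3
  expect_true(all(diff(cap_fraction_instant(atps, 2e-3, 5e-4, p)) < 0))
})

test_that("GTP enters through the saturating denominator of the competition term", {
  p <- ivt_capping(lambda = 100, theta_mM = 1)
  # analytic sign of dCF/dGTP: the competing pathway strength is
  # lambda*ATP*g/(1+g/theta), increasing and saturating in g, so CF is
  # decreasing in GTP everywhere but flattens for GTP >> theta
  g <- c(0.05, 0.2, 1, 5, 20) * 1e-3
  cf <- cap_fraction_instant(2e-3, g, 5e-4, p)
  expect_true(all(diff(cf) < 0))
  drop_low <- cf[1] - cf[2]   # below theta
  drop_high <- cf[4] - cf[5]  # far above theta (saturated denominator)
  expect_gt(drop_low, drop_high)
})

test_that("the two-condition inversion oracle reproduces the default parameters", {
  # invert CFi(3.6, 7, 0.3 mM) = 0.48 and CFi(2, 0.25, 0.05 mM) = 0.50
  # with an independent bisection on u = 1/theta
  c1 <- 0.3e-3 * (1 / 0.48 - 1) / (3.6e-3 * 7e-3)   # lambda/(1+7/theta_mM)
  c2 <- 0.05e-3 * (1 / 0.50 - 1) / (2e-3 * 0.25e-3) # lambda/(1+0.25/theta_mM)
  f <- function(u) (1 + 7 * u) / (1 + 0.25 * u) - c2 / c1
  lo <- 1e-4; hi <- 100
  for (i in 1:200) { mid <- sqrt(lo * hi); if (f(mid) < 0) lo <- mid else hi <- mid }
  theta_mM <- 1 / sqrt(lo * hi)
  lambda <- c2 * (1 + 0.25 / theta_mM)
  expect_gt(lambda, 25); expect_lt(lambda, 150)
  expect_gt(theta_mM, 0.5); expect_lt(theta_mM, 20)
  # package defaults are this inversion
  p0 <- ivt_capping()
  expect_equal(p0$lambda, lambda, tolerance = 1e-3)
  expect_equal(p0$theta * 1000, theta_mM, tolerance = 1e-3)
  expect_equal(cap_fraction_instant(3.6e-3, 7e-3, 0.3e-3, p0), 0.48,
               tolerance = 1e-3)
  expect_equal(cap_fraction_instant(2e-3, 0.25e-3, 0.05e-3, p0), 0.50,
               tolerance = 1e-3)
})

test_that("trajectory integration matches constant-condition and quadrature oracles", {
  p <- ivt_capping(lambda = 100, theta_mM = 1)
  # constant conditions: cumulative CF equals CFi exactly
  tr <- data.frame(time = seq(0, 1000, 50), atp = 2e-3, gtp = 2e-3,
                   cap = 1e-3, rate = 1e-9)
  cs <- integrate_cap_fraction(tr, p)
  cfi <- cap_fraction_instant(2e-3, 2e-3, 1e-3, p)
  expect_equal(tail(cs$cf, 1), cfi, tolerance = 1e-12)
  # zero rate: no RNA, CF reported missing
  tr0 <- transform(tr, rate = 0)
  cs0 <- integrate_cap_fraction(tr0, p)
  expect_true(all(is.na(cs0$cf)))
  expect_equal(tail(cs0$total, 1), 0)
  # two-phase trajectory with equal RNA in each phase: final CF is the
  # mean of the two CFi values; cross-check with a fine-step quadrature
  tr2 <- data.frame(time = c(seq(0, 999.999, 1), seq(1000, 2000, 1)))
  tr2$cap <- ifelse(tr2$time < 1000, 2e-3, 0.2e-3)
  tr2$atp <- 2e-3; tr2$gtp <- 2e-3; tr2$rate <- 1e-9
  cs2 <- integrate_cap_fraction(tr2, p)
  cfi_a <- cap_fraction_instant(2e-3, 2e-3, 2e-3, p)
  cfi_b <- cap_fraction_instant(2e-3, 2e-3, 0.2e-3, p)
  expect_equal(tail(cs2$cf, 1), (cfi_a + cfi_b) / 2, tolerance = 1e-3)
  # brute-force Riemann quadrature oracle at 10x finer steps
  tt <- seq(0.05, 1999.95, 0.1)        # midpoint rule
  cfi_t <- ifelse(tt < 1000, cfi_a, cfi_b)
  oracle <- sum(cfi_t * 0.1 * 1e-9) / (length(tt) * 0.1 * 1e-9)
  expect_equal(tail(cs2$cf, 1), oracle, tolerance = 1e-3)
  # malformed trajectories are rejected
  expect_error(integrate_cap_fraction(tr[c(2, 1, 3:21), ], p), "time-ordered")
  expect_error(integrate_cap_fraction(transform(tr, rate = -1), p), ">= 0")
})

test_that("cap analog consumption equals cumulative capped RNA in the reactor", {
  sim <- sim_scenario_cached("batch_capping")
  tr <- sim$trajectory
  consumed <- (tr$cap_mM[1] / 1000 * tr$volume_L[1]) -
    amount_mol(tr, "cap_mM")
  capped <- tr$capped_uM * 1e-6 * tr$volume_L
  expect_lt(max(abs(consumed - capped)), 1e-12)
  # capped RNA never exceeds total RNA
  expect_true(all(tr$capped_uM <= tr$rna_uM + 1e-12))
})

test_that("a 2 mM NTP / 2 mM cap batch lands in the predicted CF band", {
  sim <- sim_scenario_cached("batch_capping")
  cf <- tail(sim$trajectory$cf, 1)
  expect_gte(cf, 0.92)
  expect_lte(cf, 0.99)
})

test_that("Monte Carlo prediction intervals behave", {
  p0 <- ivt_capping(lambda = 100, theta_mM = 1)
  cond <- list(atp = 2e-3, gtp = 2e-3, cap = 1e-3)
  # zero covariance collapses to the point prediction
  pi0 <- cf_prediction_interval(p0, conditions = cond, seed = 7)
  expect_equal(pi0$lower, pi0$point)
  expect_equal(pi0$upper, pi0$point)
  # widening covariance widens the interval (checked at x1 vs x4)
  cv <- matrix(c(15^2, 0, 0, 0.05^2), 2)
  p1 <- ivt_capping(100, 1, cov = cv)
  p4 <- ivt_capping(100, 1, cov = 4 * cv)
  i1 <- cf_prediction_interval(p1, conditions = cond, seed = 7)
  i4 <- cf_prediction_interval(p4, conditions = cond, seed = 7)
  expect_gt(i4$upper - i4$lower, i1$upper - i1$lower)
  expect_true(all(c(i1$draws, i4$draws) >= 0 & c(i1$draws, i4$draws) <= 1))
  # deterministic given the seed
  i1b <- cf_prediction_interval(p1, conditions = cond, seed = 7)
  expect_identical(i1$draws, i1b$draws)
  expect_error(cf_prediction_interval(p1, conditions = cond, n_draws = 10),
               "n_draws")
})

test_that("capping parameter containers validate their inputs", {
  expect_error(ivt_capping(-1, 1), "> 0")
  expect_error(ivt_capping(1, 0), "> 0")
  expect_error(ivt_capping(1, 1, cov = matrix(c(1, 2, 0, 1), 2)), "symmetric")
  expect_error(ivt_capping(1, 1, cov = matrix(c(-1, 0, 0, 1), 2)),
               "semidefinite")
})
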