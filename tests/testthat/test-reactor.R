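# Reactor semantics: bolus mixing, conservation across events, continuous
# feeding, integration accuracy, and derived outputs.

test_that("policies validate their structure", {
  sol <- ivt_solution(tris = 20)
  cats <- ivt_catalysts()
  e1 <- feed_event(100, 1e-6, sol)
  e2 <- feed_event(50, 1e-6, sol)
  expect_error(feed_policy(sol, cats, 1000, events = list(e1, e2)),
               "time-ordered")
  expect_error(feed_policy(sol, cats, 1000, events = list(e2, e1),
                           continuous = list(solution = sol,
                                             profile = data.frame(
                                               time_s = 0, rate_L_s = 1e-9))),
               "not both")
  expect_error(feed_event(-1, 1e-6, sol))
  expect_error(feed_event(10, 0, sol))
})

test_that("a zero-rate continuous profile reproduces the pure batch trajectory", {
  b <- scenario_bundle()
  init <- b$policies$batch_capping$initial
  cats <- b$policies$batch_capping$catalysts
  p_batch <- feed_policy(init, cats, t_final = 3600)
  p_zero <- feed_policy(init, cats, t_final = 3600,
                        continuous = list(
                          solution = ivt_solution(),
                          profile = data.frame(time_s = c(0, 1800),
                                               rate_L_s = c(0, 0))))
  s1 <- simulate_ivt(p_batch, b$kparams$batch_capping, b$cparams,
                     b$constants, b$seq)
  s2 <- simulate_ivt(p_zero, b$kparams$batch_capping, b$cparams,
                     b$constants, b$seq)
  m <- merge(s1$trajectory, s2$trajectory, by = "time_s")
  expect_equal(m$rna_uM.x, m$rna_uM.y, tolerance = 1e-6)
  expect_equal(m$pH.x, m$pH.y, tolerance = 1e-6)
})

test_that("bolus mixing is exact dilution and volumes add", {
  b <- scenario_bundle()
  init <- b$policies$batch_capping$initial
  cats <- b$policies$batch_capping$catalysts
  # a pure-water bolus of the current reactor volume halves every total
  pol <- feed_policy(init, cats, t_final = 1200, volume_L = 1e-3,
                     events = list(feed_event(600, 1e-3, ivt_solution())))
  sim <- simulate_ivt(pol, b$kparams$batch_capping, b$cparams, b$constants,
                      b$seq)
  tr <- sim$trajectory
  i <- which(tr$time_s == 600)
  expect_length(i, 2)     # pre- and post-event states both recorded
  pre <- tr[i[1], ]; post <- tr[i[2], ]
  for (col in c("mg_mM", "atp_mM", "tris_mM", "sodium_mM", "cap_mM"))
    expect_equal(post[[col]], pre[[col]] / 2, tolerance = 1e-10)
  expect_equal(post$volume_L, 2e-3)
  # volume additivity over a bundled multi-event policy
  sim_h <- sim_scenario_cached("heuristic_fedbatch")
  pol_h <- scenario_bundle()$policies$heuristic_fedbatch
  expect_equal(tail(sim_h$trajectory$volume_L, 1),
               pol_h$volume_L + sum(vapply(pol_h$events, `[[`, numeric(1),
                                           "volume_L")),
               tolerance = 1e-12)
})

test_that("each moiety's amount changes only by what is fed", {
  sim <- sim_scenario_cached("heuristic_fedbatch")
  tr <- sim$trajectory
  pol <- scenario_bundle()$policies$heuristic_fedbatch
  fed <- function(field) sum(vapply(pol$events, function(e)
    e$solution[[field]] * e$volume_L, numeric(1)))
  # conserved spectators: total amount = initial + fed
  for (field in c("sodium", "chloride", "tris", "acetate", "mg")) {
    a0 <- pol$initial[[field]] * pol$volume_L
    a_end <- tr[[paste0(field, "_mM")]][nrow(tr)] / 1000 *
      tr$volume_L[nrow(tr)]
    expect_equal(a_end, a0 + fed(field), tolerance = 1e-8,
                 label = paste("amount of", field))
  }
})

test_that("volume and RNA amount are non-decreasing; tolerances converge", {
  sim <- sim_scenario_cached("optimized_fedbatch_highpH")
  tr <- sim$trajectory
  expect_true(all(diff(tr$volume_L) > -1e-15))
  rna_amount <- tr$rna_uM * 1e-6 * tr$volume_L
  expect_true(all(diff(rna_amount) > -1e-12))
  # grid-refinement: tightening rtol/atol by 10x moves final RNA < 0.1%
  b <- scenario_bundle()
  pol <- feed_policy(b$policies$batch_capping$initial,
                     b$policies$batch_capping$catalysts, t_final = 3600)
  s1 <- simulate_ivt(pol, b$kparams$batch_capping, b$cparams, b$constants,
                     b$seq)
  s2 <- simulate_ivt(pol, b$kparams$batch_capping, b$cparams, b$constants,
                     b$seq, rtol = 1e-9,
                     atol = c(1e-11, rep(1e-14, 14), 1e-17, 1e-17))
  r1 <- tail(s1$trajectory$rna_uM, 1); r2 <- tail(s2$trajectory$rna_uM, 1)
  expect_lt(abs(r1 - r2) / r2, 1e-3)
})

test_that("finely discretized boluses converge to the continuous-feed solution", {
  b <- scenario_bundle()
  pol_c <- b$policies$continuous_feed_literature_like
  sim_c <- sim_scenario_cached("continuous_feed_literature_like")
  discretize <- function(n) {
    pr <- pol_c$continuous$profile
    edges <- seq(0, pol_c$t_final, length.out = n + 1)
    events <- list()
    for (i in seq_len(n)) {
      t0 <- edges[i]; t1 <- edges[i + 1]
      tt <- seq(t0, t1, length.out = 21)
      rr <- pr$rate_L_s[findInterval(pmin(tt[-1] - 1e-9, pol_c$t_final),
                                     pr$time_s)]
      vol <- sum(rr * diff(tt))
      if (vol > 0)
        events[[length(events) + 1L]] <-
          feed_event((t0 + t1) / 2, vol, pol_c$continuous$solution)
    }
    feed_policy(pol_c$initial, pol_c$catalysts, t_final = pol_c$t_final,
                volume_L = pol_c$volume_L, events = events)
  }
  s12 <- simulate_ivt(discretize(12), b$kparams$continuous_feed_literature_like,
                      b$cparams, b$constants, b$seq)
  s48 <- simulate_ivt(discretize(48), b$kparams$continuous_feed_literature_like,
                      b$cparams, b$constants, b$seq)
  r_c <- tail(sim_c$trajectory$rna_uM, 1)
  d12 <- abs(tail(s12$trajectory$rna_uM, 1) - r_c) / r_c
  d48 <- abs(tail(s48$trajectory$rna_uM, 1) - r_c) / r_c
  expect_lt(d48, d12)        # refinement converges toward continuous
  expect_lt(d48, 0.02)
  # volumes agree exactly by construction
  expect_equal(tail(s48$trajectory$volume_L, 1),
               tail(sim_c$trajectory$volume_L, 1), tolerance = 1e-6)
})

test_that("RNA mass concentration converts linearly via the construct molar mass", {
  sq <- ivt_sequence_default()
  expect_equal(rna_mass_concentration(0, sq), 0)
  expect_equal(rna_mass_concentration(2e-6, sq),
               2 * rna_mass_concentration(1e-6, sq))
  # the bundled construct's molar mass puts 7 uM at ~10 g/L
  expect_equal(rna_mass_concentration(7e-6, sq), 10, tolerance = 0.01)
})

test_that("rate decomposition is exact and trivial factors stay at unity", {
  sim <- sim_scenario_cached("batch_capping")
  d <- decompose_rate_decline(sim)
  expect_lt(max(abs(d$product - d$rate_ratio)), 1e-6)
  # no feeds: catalyst dilution factor is identically 1
  expect_equal(d$f_catalyst, rep(1, nrow(d)), tolerance = 1e-12)
})

test_that("simulation summaries and tidies expose the main quantities", {
  sim <- sim_scenario_cached("batch_capping")
  g <- glance(sim)
  expect_true(all(c("rna_uM", "rna_gL", "cf", "pH", "effective_salt_mM",
                    "sigma", "peak_sigma") %in% names(g)))
  td <- tidy(sim)
  expect_true(all(c("time_s", "variable", "value") %in% names(td)))
  pl <- autoplot(sim)
  expect_s3_class(pl, "ggplot")
  pl2 <- plot_rate_decomposition(sim)
  expect_s3_class(pl2, "ggplot")
})
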