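# Feed-policy optimization: setpoint-tracking objective over initial
# conditions and bolus amounts, derivative-free search (Latin hypercube
# exploration + Nelder-Mead polish) over a box-bounded decision vector.

#' Setpoint-tracking objective for fed-batch policy optimization
#'
#' The scalarized objective
#' \deqn{\nu_{NTP} \sum_{N} \sum_{t_i \in t_N} ([NTP]_{F,t_i} - [NTP]_{sp})^2
#'   + \nu_{pH} \sum_{t_i \in t_{pH}} (pH_{F,t_i} - pH_{sp})^2
#'   - \nu_{RNA} [RNA]_{t_f}}
#' with NTP concentrations in mM, pH in pH units and RNA in uM (so the
#' default unit weights put the three terms on comparable scales for the
#' reference scenarios).
#'
#' @param ntp_sp_mM per-NTP setpoint (mM).
#' @param ph_sp pH setpoint.
#' @param t_final horizon (s).
#' @param t_ntp,t_ph evaluation time sets (s); defaults: uniform 5-min grid.
#' @param nu_ntp,nu_ph,nu_rna nonnegative weights.
#' @param sigma_max optional supersaturation cap (policy infeasible if the
#'   peak sigma exceeds it).
#' @param mg_bound_scale multiplier on the Mg feed upper bounds (used by
#'   [low_ph_variant()] to reduce Mg feeding slightly).
#' @return an `ivt_objective`.
#' @export
ivt_objective <- function(ntp_sp_mM = 2, ph_sp = 8.0, t_final = 10800,
                          t_ntp = seq(300, t_final, by = 300),
                          t_ph = seq(300, t_final, by = 300),
                          nu_ntp = 1, nu_ph = 1, nu_rna = 1,
                          sigma_max = NULL, mg_bound_scale = 1) {
  stopifnot(nu_ntp >= 0, nu_ph >= 0, nu_rna >= 0, t_final > 0,
            all(t_ntp >= 0 & t_ntp <= t_final),
            all(t_ph >= 0 & t_ph <= t_final))
  structure(list(ntp_sp_mM = ntp_sp_mM, ph_sp = ph_sp, t_final = t_final,
                 t_ntp = t_ntp, t_ph = t_ph, nu_ntp = nu_ntp, nu_ph = nu_ph,
                 nu_rna = nu_rna, sigma_max = sigma_max,
                 mg_bound_scale = mg_bound_scale),
            class = "ivt_objective")
}

#' Low-pH (anti-precipitation) variant of an objective
#'
#' Moves pH tracking from the whole trajectory at setpoint 8.0 to the end
#' of the process at setpoint 7.3 (a tail window, t >= 0.9 t_f) and reduces
#' the Mg feed bounds slightly. Idempotent.
#'
#' @param obj an [ivt_objective()].
#' @param ph_end end-of-process pH setpoint.
#' @param tail_frac fraction of the horizon defining the tail window.
#' @param mg_scale Mg-feed bound multiplier.
#' @return an `ivt_objective`.
#' @export
low_ph_variant <- function(obj, ph_end = 7.3, tail_frac = 0.9,
                           mg_scale = 0.85) {
  stopifnot(inherits(obj, "ivt_objective"))
  obj$ph_sp <- ph_end
  obj$t_ph <- obj$t_ph[obj$t_ph >= tail_frac * obj$t_final]
  if (length(obj$t_ph) == 0) obj$t_ph <- obj$t_final
  obj$mg_bound_scale <- mg_scale
  obj
}

#' Decision-vector template for policy optimization
#'
#' Encodes a feeding policy F as a box-bounded numeric vector: three initial
#' condition entries (initial Mg, initial tris, initial per-NTP
#' concentration, mM) followed by three entries per bolus event (per-NTP
#' feed concentration, Mg feed concentration, NaOH feed concentration of a
#' fixed-volume bolus, mM). Event times sit on a fixed uniform grid; only
#' amounts are optimized, keeping the search space a box.
#'
#' @param n_events number of bolus events.
#' @param t_final horizon (s).
#' @param catalysts an [ivt_catalysts()].
#' @param volume_L initial volume (L).
#' @param volume_event_L bolus volume (L).
#' @param cap_mM initial cap analog (mM).
#' @param lower,upper named bound overrides: entries `mg0`, `tris0`, `ntp0`,
#'   `ntp_feed`, `mg_feed`, `naoh_feed` (mM).
#' @param seq an [ivt_sequence()] (apportions NTP feeds across bases).
#' @return an `ivt_decision_template` with `lower`/`upper` vectors.
#' @export
decision_template <- function(n_events = 9, t_final = 10800,
                              catalysts = ivt_catalysts(),
                              volume_L = 1e-3, volume_event_L = 20e-6,
                              cap_mM = 0, lower = list(), upper = list(),
                              seq = ivt_sequence_default()) {
  lo <- list(mg0 = 2, tris0 = 5, ntp0 = 0.5,
             ntp_feed = 0, mg_feed = 0, naoh_feed = 0)
  hi <- list(mg0 = 30, tris0 = 60, ntp0 = 6,
             ntp_feed = 400, mg_feed = 200, naoh_feed = 400)
  lo[names(lower)] <- lower
  hi[names(upper)] <- upper
  ev_names <- as.vector(t(outer(seq_len(n_events),
                                c("ntp_feed", "mg_feed", "naoh_feed"),
                                function(i, s) paste0(s, "_", i))))
  nm <- c("mg0", "tris0", "ntp0", ev_names)
  lower_v <- c(lo$mg0, lo$tris0, lo$ntp0,
               rep(c(lo$ntp_feed, lo$mg_feed, lo$naoh_feed), n_events))
  upper_v <- c(hi$mg0, hi$tris0, hi$ntp0,
               rep(c(hi$ntp_feed, hi$mg_feed, hi$naoh_feed), n_events))
  names(lower_v) <- names(upper_v) <- nm
  structure(list(n_events = n_events, t_final = t_final,
                 event_times = seq(t_final / (n_events + 1),
                                   t_final * n_events / (n_events + 1),
                                   length.out = n_events),
                 catalysts = catalysts, volume_L = volume_L,
                 volume_event_L = volume_event_L, cap_mM = cap_mM,
                 lower = lower_v, upper = upper_v, seq = seq),
            class = "ivt_decision_template")
}

#' Decode a decision vector into a feed policy
#'
#' @param F numeric decision vector (within the template bounds).
#' @param template an [decision_template()].
#' @param constants an [ivt_constants()] (initial solution titrated to
#'   pH 8.0).
#' @return a [feed_policy()].
#' @export
decode_policy <- function(F, template, constants = ivt_constants()) {
  stopifnot(inherits(template, "ivt_decision_template"),
            length(F) == length(template$lower))
  if (any(F < template$lower - 1e-9) || any(F > template$upper + 1e-9))
    stop("decision vector outside box bounds")
  sq <- template$seq
  w <- sq$counts / sq$length
  init <- adjust_to_pH(ivt_solution(
    atp = F[3] * 4 * w[["A"]], utp = F[3] * 4 * w[["U"]],
    ctp = F[3] * 4 * w[["C"]], gtp = F[3] * 4 * w[["G"]],
    mg = F[1], tris = F[2], cap = template$cap_mM,
    sodium = 2 * 4 * F[3] + 4 * template$cap_mM,
    na_counterions = FALSE), 8.0, constants)
  events <- list()
  for (i in seq_len(template$n_events)) {
    v <- F[3 + (i - 1) * 3 + 1:3]
    if (sum(v) <= 0) next
    feed <- ivt_solution(
      atp = v[1] * 4 * w[["A"]], utp = v[1] * 4 * w[["U"]],
      ctp = v[1] * 4 * w[["C"]], gtp = v[1] * 4 * w[["G"]],
      mg = v[2], acetate = 2 * v[2], strong_base = v[3],
      sodium = 2 * 4 * v[1], na_counterions = FALSE)
    events[[length(events) + 1L]] <-
      feed_event(template$event_times[i], template$volume_event_L, feed)
  }
  feed_policy(init, template$catalysts, t_final = template$t_final,
              volume_L = template$volume_L, events = events)
}

#' Evaluate the setpoint-tracking objective for a decision vector
#'
#' Decodes F, simulates, and scores tracking of all four NTPs over `t_ntp`,
#' pH over `t_ph`, and final RNA. A failed simulation (or violation of
#' `sigma_max`) returns a large finite penalty rather than an error so that
#' derivative-free optimizers can continue.
#'
#' @param F decision vector.
#' @param obj an [ivt_objective()].
#' @param template an [decision_template()].
#' @param kparams,cparams,constants,seq model parameters.
#' @param detail if `TRUE` return a list with the simulation and the three
#'   objective terms.
#' @return scalar objective (or a list when `detail = TRUE`).
#' @export
evaluate_objective <- function(F, obj, template,
                               kparams = ivt_kinetics(10^3.93),
                               cparams = ivt_capping(),
                               constants = ivt_constants(),
                               seq = ivt_sequence_default(),
                               detail = FALSE) {
  stopifnot(inherits(obj, "ivt_objective"))
  penalty <- 1e6
  sim <- tryCatch({
    pol <- decode_policy(F, template, constants)
    simulate_ivt(pol, kparams, cparams, constants, seq)
  }, error = function(e) e)
  if (inherits(sim, "error")) {
    if (!detail) return(penalty)
    return(list(objective = penalty, error = conditionMessage(sim)))
  }
  tr <- sim$trajectory
  if (!is.null(obj$sigma_max) && max(tr$sigma) > obj$sigma_max) {
    if (!detail) return(penalty)
    return(list(objective = penalty, error = "sigma_max violated", sim = sim))
  }
  at <- function(col, times)
    stats::approx(tr$time_s, tr[[col]], xout = times, ties = "ordered")$y
  ntp_term <- sum(vapply(c("atp_mM", "utp_mM", "ctp_mM", "gtp_mM"),
                         function(cl) sum((at(cl, obj$t_ntp) - obj$ntp_sp_mM)^2),
                         numeric(1)))
  ph_term <- sum((at("pH", obj$t_ph) - obj$ph_sp)^2)
  rna_final <- tr$rna_uM[nrow(tr)]
  val <- obj$nu_ntp * ntp_term + obj$nu_ph * ph_term - obj$nu_rna * rna_final
  if (!detail) return(val)
  list(objective = val, ntp_term = ntp_term, ph_term = ph_term,
       rna_uM = rna_final, sim = sim)
}

#' Optimize a feed policy under a setpoint-tracking objective
#'
#' Derivative-free hybrid: a seeded Latin-hypercube exploration of the box
#' (optionally around a supplied start) followed by a bounded Nelder-Mead
#' polish from the best candidate, all within a fixed evaluation budget.
#' Deterministic given the seed; the returned best objective is never worse
#' than any evaluated candidate.
#'
#' @param obj an [ivt_objective()].
#' @param template an [decision_template()]; its Mg feed upper bounds are
#'   scaled by `obj$mg_bound_scale`.
#' @param seed integer seed.
#' @param budget total objective-evaluation budget (>= 1).
#' @param start optional starting decision vector (evaluated first).
#' @param explore_frac fraction of the budget spent on space-filling
#'   exploration before the local polish.
#' @param ... passed to [evaluate_objective()] (model parameters).
#' @return list: `par` (best decision vector), `objective`, `policy`
#'   (decoded best), `trace` (tibble of all evaluations).
#' @export
optimize_policy <- function(obj, template, seed = 1, budget = 60,
                            start = NULL, explore_frac = 0.5, ...) {
  stopifnot(budget >= 1)
  lower <- template$lower
  upper <- template$upper
  mg_idx <- grep("^mg_feed_", names(upper))
  upper[mg_idx] <- upper[mg_idx] * obj$mg_bound_scale
  n <- length(lower)

  evals <- list()
  n_eval <- 0L
  f_wrap <- function(x) {
    x <- pmin(pmax(x, lower), upper)   # project; keeps Nelder-Mead feasible
    if (n_eval >= budget) return(Inf)
    v <- evaluate_objective(x, obj, template, ...)
    n_eval <<- n_eval + 1L
    evals[[n_eval]] <<- c(eval = n_eval, objective = v,
                          stats::setNames(as.numeric(x), names(lower)))
    v
  }

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  n_explore <- max(1L, min(budget, ceiling(budget * explore_frac)))
  X <- lhs::randomLHS(n_explore, n)
  cand <- t(lower + t(X) * (upper - lower))
  if (!is.null(start)) cand[1, ] <- pmin(pmax(start, lower), upper)
  for (i in seq_len(nrow(cand))) f_wrap(cand[i, ])

  tr0 <- do.call(rbind, evals)
  best_i <- which.min(tr0[, "objective"])
  best_x <- tr0[best_i, -(1:2)]
  remaining <- budget - n_eval
  if (remaining > 2 && is.finite(tr0[best_i, "objective"])) {
    stats::optim(best_x, f_wrap, method = "Nelder-Mead",
                 control = list(maxit = remaining * 2, warn.1d.NelderMead = FALSE))
  }
  tr <- tibble::as_tibble(do.call(rbind, evals), .name_repair = "minimal")
  best <- which.min(tr$objective)
  par <- pmin(pmax(as.numeric(tr[best, -(1:2)]), lower), upper)
  names(par) <- names(lower)
  if (!is.finite(tr$objective[best]) || tr$objective[best] >= 1e6)
    stop("no feasible policy found within the budget; all candidates ",
         "failed or violated constraints")
  list(par = par, objective = tr$objective[best],
       policy = decode_policy(par, template),
       trace = tr)
}
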