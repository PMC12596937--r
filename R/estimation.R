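# Calibration of the capping parameters (lambda, theta) by maximum
# likelihood from batch cap-fraction measurements, and D-optimal selection
# of calibration experiments over initial ATP/GTP/cap concentrations.

#' Reference calibration measurements (two-batch design)
#'
#' The two-condition calibration layout used throughout the package:
#' initial concentrations of the two designed batch experiments with the
#' model-predicted CFs under the package's default (initial) capping
#' parameters and the experimentally measured values they are calibrated
#' against.
#' @return tibble with columns `atp_mM`, `gtp_mM`, `cap_mM`, `cf_measured`,
#'   `cf_sd`.
#' @export
capping_calibration_data <- function() {
  tibble::tibble(
    atp_mM = c(3.6, 2), gtp_mM = c(7, 0.25), cap_mM = c(0.3, 0.05),
    cf_measured = c(0.47, 0.83), cf_sd = c(0.10, 0.05))
}

#' Batch trajectory for a capping calibration experiment
#'
#' Simulates a batch with the given initial ATP/GTP/cap and a standard
#' calibration background (UTP = CTP = 2 mM, Mg covering the NTP pool,
#' 40 mM tris at pH 8) and returns the minimal trajectory needed to
#' integrate the cap fraction under arbitrary capping parameters.
#'
#' Because cap-analog consumption (uM scale) is far below its mM-scale
#' inventory, the concentration/rate trajectory is insensitive to the
#' capping parameters themselves; a single simulation therefore serves for
#' all parameter values during fitting and Monte Carlo propagation.
#'
#' @param atp_mM,gtp_mM,cap_mM initial concentrations (mM).
#' @param kparams,cparams,constants,seq model parameters.
#' @param t_final batch horizon (s).
#' @param catalysts an [ivt_catalysts()].
#' @return tibble with columns `time`, `atp`, `gtp`, `cap` (M), `rate` (M/s).
#' @export
capping_batch_trajectory <- function(atp_mM, gtp_mM, cap_mM,
                                     kparams = ivt_kinetics(),
                                     cparams = ivt_capping(),
                                     constants = ivt_constants(),
                                     seq = ivt_sequence_default(),
                                     t_final = 7200,
                                     catalysts = ivt_catalysts()) {
  ntp_tot <- atp_mM + gtp_mM + 4
  init <- adjust_to_pH(ivt_solution(
    atp = atp_mM, utp = 2, ctp = 2, gtp = gtp_mM, cap = cap_mM,
    mg = ntp_tot + 2, tris = 40,
    sodium = 2 * (atp_mM + gtp_mM + 4) + 4 * cap_mM,
    na_counterions = FALSE), 8.0, constants)
  pol <- feed_policy(init, catalysts, t_final = t_final)
  sim <- simulate_ivt(pol, kparams, cparams, constants, seq)
  tr <- sim$trajectory
  tibble::tibble(time = tr$time_s, atp = tr$atp_mM / 1000,
                 gtp = tr$gtp_mM / 1000, cap = tr$cap_mM / 1000,
                 rate = tr$rate_Ms)
}

#' Predict the final cap fraction of a calibration batch
#'
#' Either by full batch integration over a (cached) trajectory or from the
#' instantaneous CF at the initial concentrations.
#'
#' @param atp_mM,gtp_mM,cap_mM initial concentrations (mM).
#' @param params an [ivt_capping()].
#' @param mode `"integrated"` (default) or `"instantaneous"`.
#' @param trajectory optional precomputed [capping_batch_trajectory()]
#'   (ignored for instantaneous mode).
#' @param ... passed to [capping_batch_trajectory()] when it must be built.
#' @return scalar predicted CF.
#' @export
predict_cf_batch <- function(atp_mM, gtp_mM, cap_mM, params = ivt_capping(),
                             mode = c("integrated", "instantaneous"),
                             trajectory = NULL, ...) {
  mode <- match.arg(mode)
  if (mode == "instantaneous")
    return(unname(cap_fraction_instant(atp_mM / 1000, gtp_mM / 1000,
                                       cap_mM / 1000, params)))
  if (is.null(trajectory))
    trajectory <- capping_batch_trajectory(atp_mM, gtp_mM, cap_mM, ...)
  cs <- integrate_cap_fraction(trajectory, params)
  utils::tail(cs$cf, 1)
}

#' Maximum-likelihood calibration of the capping parameters
#'
#' Fits (lambda, theta) to cap-fraction measurements by maximizing an
#' independent-Gaussian likelihood with per-measurement standard
#' deviations. The fit is performed in log-parameter space (guaranteeing
#' positive estimates); the covariance is the inverse observed information
#' at the optimum, mapped back to `(lambda, theta_mM)` by the delta method.
#' Truncation of the Gaussian to [0, 1] is ignored in the likelihood.
#'
#' @param measurements data frame with columns `atp_mM`, `gtp_mM`, `cap_mM`,
#'   `cf_measured`, `cf_sd` (see [capping_calibration_data()]).
#' @param mode CF prediction used inside the fit: `"integrated"` full batch
#'   integration (default) or `"instantaneous"`.
#' @param init initial [ivt_capping()] estimate.
#' @param ... passed to [capping_batch_trajectory()] (integrated mode).
#' @return an `ivt_cf_fit`: list with `params` (an [ivt_capping()] with
#'   covariance), `logLik`, `fitted` (tibble with predictions), `mode`,
#'   optimizer diagnostics. Supports [tidy()] and [glance()].
#' @export
mle_fit_capping <- function(measurements, mode = c("integrated",
                                                   "instantaneous"),
                            init = ivt_capping(), ...) {
  mode <- match.arg(mode)
  m <- tibble::as_tibble(measurements)
  need <- c("atp_mM", "gtp_mM", "cap_mM", "cf_measured", "cf_sd")
  if (!all(need %in% names(m)))
    stop("measurements must have columns ", paste(need, collapse = ", "))
  if (any(m$cf_sd <= 0)) stop("cf_sd must be > 0")
  if (any(m$cf_measured < 0 | m$cf_measured > 1))
    stop("cf_measured must lie in [0, 1]")
  if (length(unique(m$gtp_mM)) < 2)
    stop("need measurements at >= 2 distinct GTP levels: with a single ",
         "GTP level only the composite lambda/(1 + GTP/theta) is ",
         "identifiable, not lambda and theta separately")

  trajs <- NULL
  if (mode == "integrated") {
    key <- paste(m$atp_mM, m$gtp_mM, m$cap_mM)
    uk <- !duplicated(key)
    trajs <- lapply(which(uk), function(i)
      capping_batch_trajectory(m$atp_mM[i], m$gtp_mM[i], m$cap_mM[i],
                               cparams = init, ...))
    names(trajs) <- key[uk]
  }
  predict_all <- function(p) {
    vapply(seq_len(nrow(m)), function(i) {
      if (mode == "instantaneous")
        predict_cf_batch(m$atp_mM[i], m$gtp_mM[i], m$cap_mM[i], p,
                         mode = "instantaneous")
      else
        predict_cf_batch(m$atp_mM[i], m$gtp_mM[i], m$cap_mM[i], p,
                         trajectory = trajs[[paste(m$atp_mM[i], m$gtp_mM[i],
                                                   m$cap_mM[i])]])
    }, numeric(1))
  }
  nll <- function(lp) {
    p <- ivt_capping(exp(lp[1]), exp(lp[2]) * 1000)
    pred <- predict_all(p)
    sum(0.5 * ((pred - m$cf_measured) / m$cf_sd)^2)
  }
  lp0 <- c(log(init$lambda), log(init$theta))
  fit <- stats::optim(lp0, nll, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-12))
  fit <- stats::optim(fit$par, nll, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-12))
  H <- stats::optimHess(fit$par, nll)
  ev <- eigen(H, symmetric = TRUE)
  if (min(ev$values) < 1e-8 * max(abs(ev$values))) {
    dir <- ev$vectors[, which.min(ev$values)]
    stop("flat likelihood: the design does not identify the direction ",
         sprintf("%.2f*log(lambda) %+.2f*log(theta)", dir[1], dir[2]),
         "; add measurements at additional GTP levels")
  }
  cov_log <- solve(H)
  lam <- exp(fit$par[1]); th <- exp(fit$par[2])
  D <- diag(c(lam, th * 1000))        # d(lambda, theta_mM)/d(log params)
  cov_nat <- D %*% cov_log %*% D
  cov_nat <- (cov_nat + t(cov_nat)) / 2
  params <- ivt_capping(lam, th * 1000, cov = cov_nat)
  pred <- predict_all(params)
  ll <- sum(stats::dnorm(m$cf_measured, pred, m$cf_sd, log = TRUE))
  structure(list(params = params, logLik = ll,
                 fitted = dplyr::mutate(m, cf_predicted = pred,
                                        residual = m$cf_measured - pred),
                 mode = mode, convergence = fit$convergence,
                 nll = fit$value, trajectories = trajs),
            class = "ivt_cf_fit")
}

#' @export
print.ivt_cf_fit <- function(x, ...) {
  cat("<ivt_cf_fit> (", x$mode, " CF predictions)\n", sep = "")
  print(x$params)
  cat("  logLik", round(x$logLik, 3), "on", nrow(x$fitted), "measurements\n")
  invisible(x)
}

#' @export
tidy.ivt_cf_fit <- function(x, ...) {
  se <- sqrt(diag(x$params$cov))
  est <- c(x$params$lambda, x$params$theta * 1000)
  tibble::tibble(term = c("lambda", "theta_mM"), estimate = est,
                 std.error = se,
                 conf.low = est - 1.96 * se, conf.high = est + 1.96 * se)
}

#' @export
glance.ivt_cf_fit <- function(x, ...) {
  tibble::tibble(logLik = x$logLik, nobs = nrow(x$fitted),
                 df.residual = nrow(x$fitted) - 2,
                 deviance = 2 * x$nll, convergence = x$convergence)
}

# gradient of the predicted CF w.r.t. (lambda, theta_mM)
cf_gradient <- function(atp_mM, gtp_mM, cap_mM, params,
                        mode = "instantaneous", trajectory = NULL) {
  if (mode == "instantaneous") {
    a <- atp_mM / 1000; g <- gtp_mM / 1000; c0 <- cap_mM / 1000
    lam <- params$lambda; th <- params$theta
    B <- lam * a * g / (1 + g / th)
    d <- (c0 + B)^2
    dlam <- -c0 * B / lam / d
    dth_M <- -c0 * (B * (g / th^2) / (1 + g / th)) / d
    return(c(lambda = dlam, theta_mM = dth_M / 1000))
  }
  # central finite differences for the integrated prediction
  f <- function(lam, th_mM)
    predict_cf_batch(atp_mM, gtp_mM, cap_mM, ivt_capping(lam, th_mM),
                     mode = "integrated", trajectory = trajectory)
  hl <- params$lambda * 1e-5; ht <- params$theta * 1000 * 1e-5
  c(lambda = (f(params$lambda + hl, params$theta * 1000) -
                f(params$lambda - hl, params$theta * 1000)) / (2 * hl),
    theta_mM = (f(params$lambda, params$theta * 1000 + ht) -
                  f(params$lambda, params$theta * 1000 - ht)) / (2 * ht))
}

#' Fisher information matrix of a calibration design
#'
#' Sum over planned experiments of the outer products of the CF prediction
#' gradient with respect to `(lambda, theta_mM)`, weighted by the inverse
#' measurement variance. Symmetric positive semidefinite; one experiment
#' alone has rank <= 1 and cannot identify both parameters.
#'
#' @param design data frame with columns `atp_mM`, `gtp_mM`, `cap_mM`.
#' @param params an [ivt_capping()] (the prior/initial estimate at which
#'   the design is linearized).
#' @param sd measurement standard deviation (scalar or per experiment).
#' @param mode `"instantaneous"` (default; closed-form gradients) or
#'   `"integrated"`.
#' @param ... passed to [capping_batch_trajectory()] in integrated mode.
#' @return 2x2 information matrix.
#' @export
fisher_information <- function(design, params = ivt_capping(), sd = 0.05,
                               mode = c("instantaneous", "integrated"), ...) {
  mode <- match.arg(mode)
  d <- tibble::as_tibble(design)
  stopifnot(all(c("atp_mM", "gtp_mM", "cap_mM") %in% names(d)),
            nrow(d) >= 1)
  sd <- rep_len(sd, nrow(d))
  M <- matrix(0, 2, 2, dimnames = list(c("lambda", "theta_mM"),
                                       c("lambda", "theta_mM")))
  for (i in seq_len(nrow(d))) {
    traj <- if (mode == "integrated")
      capping_batch_trajectory(d$atp_mM[i], d$gtp_mM[i], d$cap_mM[i],
                               cparams = params, ...) else NULL
    g <- cf_gradient(d$atp_mM[i], d$gtp_mM[i], d$cap_mM[i], params,
                     mode = mode, trajectory = traj)
    M <- M + tcrossprod(g) / sd[i]^2
  }
  M
}

#' D-optimal design of capping calibration experiments
#'
#' Chooses `n_experiments` initial (ATP, GTP, cap) triplets inside box
#' bounds to maximize det of the Fisher information of `(lambda, theta)`,
#' by seeded random (Latin hypercube) search followed by a Nelder-Mead
#' polish. Deterministic given the seed; the returned determinant is by
#' construction at least that of every random candidate evaluated
#' (`n_random` >= 1000 of them by default).
#'
#' @param n_experiments number of experiments (>= 2 for two parameters).
#' @param bounds list with numeric vectors `lower` and `upper`, each named
#'   `atp_mM`, `gtp_mM`, `cap_mM`.
#' @param params linearization point ([ivt_capping()]).
#' @param sd measurement standard deviation.
#' @param seed integer seed.
#' @param n_random random designs evaluated before polishing.
#' @param mode CF prediction mode for the information matrix.
#' @return an `ivt_design`: list with `design` (tibble), `det_fim`,
#'   `fim`, `n_random`, `best_random_det`.
#' @export
d_optimal_design <- function(n_experiments = 2,
                             bounds = list(
                               lower = c(atp_mM = 0.25, gtp_mM = 0.1,
                                         cap_mM = 0.02),
                               upper = c(atp_mM = 5, gtp_mM = 8,
                                         cap_mM = 1)),
                             params = ivt_capping(), sd = 0.05, seed = 1,
                             n_random = 1000,
                             mode = "instantaneous") {
  if (n_experiments < 2)
    stop("need >= 2 experiments to identify the two capping parameters")
  lo <- bounds$lower[c("atp_mM", "gtp_mM", "cap_mM")]
  hi <- bounds$upper[c("atp_mM", "gtp_mM", "cap_mM")]
  if (any(is.na(lo)) || any(is.na(hi))) stop("bounds must name atp_mM, gtp_mM, cap_mM")
  if (all(hi <= lo)) stop("degenerate bounds: zero search volume")
  k <- 3 * n_experiments
  to_design <- function(x)
    tibble::tibble(atp_mM = x[seq(1, k, 3)], gtp_mM = x[seq(2, k, 3)],
                   cap_mM = x[seq(3, k, 3)])
  obj <- function(x) {
    x <- pmin(pmax(x, rep(lo, n_experiments)), rep(hi, n_experiments))
    -det(fisher_information(to_design(x), params, sd, mode = mode))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  X <- lhs::randomLHS(n_random, k)
  cand <- t(rep(lo, n_experiments) + t(X) * rep(hi - lo, n_experiments))
  vals <- apply(cand, 1, obj)
  best <- which.min(vals)
  best_random_det <- -vals[best]
  pol <- stats::optim(cand[best, ], obj, method = "Nelder-Mead",
                      control = list(maxit = 800, reltol = 1e-12))
  x <- pmin(pmax(pol$par, rep(lo, n_experiments)), rep(hi, n_experiments))
  design <- to_design(x)
  fim <- fisher_information(design, params, sd, mode = mode)
  structure(list(design = design, det_fim = det(fim), fim = fim,
                 n_random = n_random, best_random_det = best_random_det,
                 seed = seed),
            class = "ivt_design")
}

#' @export
print.ivt_design <- function(x, ...) {
  cat("<ivt_design> det(FIM) =", format(x$det_fim, digits = 5),
      "(best of", x$n_random, "random designs:",
      format(x$best_random_det, digits = 5), ")\n")
  print(x$design)
  invisible(x)
}
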