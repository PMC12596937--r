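# Co-transcriptional capping: competition between the AG cap analog and
# ATP/GTP at initiation, expressed through the two identifiable composite
# parameters lambda (M^-1) and theta (M).

#' Capping competition parameters
#'
#' The quasi-steady-state initiation competition model is identifiable only
#' through two composites of the elementary initiation rate constants:
#' `lambda` (M^-1), the strength of the two-step ATP+GTP pathway relative to
#' one-step cap incorporation, and `theta` (a GTP half-effect concentration,
#' user-facing in mM). A covariance matrix over `(lambda, theta_mM)` carries
#' calibration uncertainty for Monte Carlo prediction intervals.
#'
#' @param lambda competition coefficient (M^-1), > 0.
#' @param theta_mM GTP half-effect concentration (mM), > 0.
#' @param cov 2x2 symmetric PSD covariance of `(lambda, theta_mM)`.
#' @return an `ivt_capping` parameter object (theta stored in M).
#' @export
ivt_capping <- function(lambda = 133.36, theta_mM = 0.7494,
                        cov = matrix(0, 2, 2)) {
  if (lambda <= 0 || theta_mM <= 0) stop("lambda and theta must be > 0")
  cov <- as.matrix(cov)
  if (!isTRUE(all.equal(cov, t(cov))) || any(eigen(cov, symmetric = TRUE,
                                                   only.values = TRUE)$values < -1e-10))
    stop("cov must be symmetric positive semidefinite")
  structure(list(lambda = lambda, theta = theta_mM / 1000, cov = cov),
            class = "ivt_capping")
}

#' @export
print.ivt_capping <- function(x, ...) {
  cat("<ivt_capping> lambda =", signif(x$lambda, 5), "M^-1; theta =",
      signif(x$theta * 1000, 5), "mM\n")
  if (any(x$cov != 0)) {
    cat("  covariance (lambda, theta_mM):\n"); print(signif(x$cov, 4))
  }
  invisible(x)
}

#' Instantaneous cap fraction
#'
#' Fraction of newly initiated transcripts that incorporate the AG cap
#' analog rather than ATP then GTP:
#' \deqn{CF_i = \frac{[cap]}{[cap] + \lambda [ATP][GTP] / (1 + [GTP]/\theta)}}
#' Increasing in cap, decreasing in ATP. When both the cap analog and the
#' ATP.GTP product are zero no transcript can initiate; the value is defined
#' as 0 with a warning.
#'
#' @param atp,gtp,cap concentrations (M), vectorized.
#' @param params an [ivt_capping()] set.
#' @return cap fraction in [0, 1].
#' @export
cap_fraction_instant <- function(atp, gtp, cap, params = ivt_capping()) {
  stopifnot(all(atp >= 0), all(gtp >= 0), all(cap >= 0))
  comp <- params$lambda * atp * gtp / (1 + gtp / params$theta)
  out <- ifelse(cap + comp > 0, cap / (cap + comp), 0)
  if (any(cap + comp == 0))
    warning("cap analog and ATP.GTP pathway both absent: CFi set to 0 ",
            "(no transcription possible)")
  out
}

#' Integrate the cap fraction over a reactor trajectory
#'
#' Accumulates capped and total RNA along a time series of solution
#' conditions and RNA production rate by trapezoidal quadrature of
#' \eqn{d(capped)/dt = CF_i \, r} and \eqn{d(cap)/dt = -CF_i \, r},
#' yielding the cumulative cap fraction. For constant conditions the
#' cumulative CF equals the instantaneous CFi exactly.
#'
#' @param trajectory data frame with columns `time` (s, increasing),
#'   `atp`, `gtp`, `cap` (M) and `rate` (RNA production, M/s, >= 0).
#' @param params an [ivt_capping()] set.
#' @return tibble time series: `time`, `cfi`, `capped` and `total` RNA (M),
#'   `cap_remaining` (M), cumulative `cf` (NA while total RNA is 0).
#' @export
integrate_cap_fraction <- function(trajectory, params = ivt_capping()) {
  tr <- as.data.frame(trajectory)
  need <- c("time", "atp", "gtp", "cap", "rate")
  if (!all(need %in% names(tr)))
    stop("trajectory must have columns ", paste(need, collapse = ", "))
  if (is.unsorted(tr$time)) stop("trajectory must be time-ordered")
  if (any(tr$rate < 0)) stop("rates must be >= 0")
  cfi <- cap_fraction_instant(tr$atp, tr$gtp, tr$cap, params)
  n <- nrow(tr)
  dt <- diff(tr$time)
  inc_tot <- c(0, dt * (tr$rate[-n] + tr$rate[-1]) / 2)
  inc_cap <- c(0, dt * (cfi[-n] * tr$rate[-n] + cfi[-1] * tr$rate[-1]) / 2)
  capped <- cumsum(inc_cap)
  total <- cumsum(inc_tot)
  cap_rem <- tr$cap[1] - capped
  if (any(cap_rem < -1e-12 * max(tr$cap[1], 1e-12)))
    stop("cap analog driven below zero; refine the trajectory time step")
  tibble::tibble(time = tr$time, cfi = cfi, capped = capped, total = total,
                 cap_remaining = pmax(cap_rem, 0),
                 cf = ifelse(total > 0, capped / total, NA_real_))
}

#' Monte Carlo prediction interval for the cap fraction
#'
#' Central 95% interval of a CF prediction over draws of `(lambda,
#' theta_mM)` from the parameter covariance. Draws violating positivity are
#' rejected (and counted); the interval is deterministic given the seed.
#'
#' @param params an [ivt_capping()] with covariance.
#' @param predict_fn function of an `ivt_capping` returning the scalar CF
#'   prediction to propagate (e.g. a batch-simulation wrapper, or the
#'   default: instantaneous CF at `conditions`).
#' @param conditions named list/vector `atp`, `gtp`, `cap` (M); used by the
#'   default `predict_fn`.
#' @param n_draws Monte Carlo sample size (>= 1000).
#' @param seed integer seed.
#' @param level interval level (default 0.95).
#' @return list: `lower`, `upper`, `point`, `draws` (accepted CF draws),
#'   `n_rejected`.
#' @export
cf_prediction_interval <- function(params, predict_fn = NULL,
                                   conditions = NULL, n_draws = 2000,
                                   seed = 1, level = 0.95) {
  stopifnot(inherits(params, "ivt_capping"), n_draws >= 1000)
  if (is.null(predict_fn)) {
    stopifnot(!is.null(conditions))
    predict_fn <- function(p)
      cap_fraction_instant(conditions[["atp"]], conditions[["gtp"]],
                           conditions[["cap"]], p)
  }
  point <- predict_fn(params)
  mu <- c(params$lambda, params$theta * 1000)
  if (all(params$cov == 0))
    return(list(lower = point, upper = point, point = point,
                draws = rep(point, n_draws), n_rejected = 0L))
  # symmetric square root handles PSD (possibly singular) covariances
  es <- eigen(params$cov, symmetric = TRUE)
  rt <- es$vectors %*% diag(sqrt(pmax(es$values, 0)), 2) %*% t(es$vectors)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n_rej <- 0L
  draws <- numeric(n_draws)
  got <- 0L
  while (got < n_draws) {
    m <- n_draws - got
    z <- matrix(stats::rnorm(2 * m), 2, m)
    par <- mu + rt %*% z
    keep <- par[1, ] > 0 & par[2, ] > 0
    n_rej <- n_rej + sum(!keep)
    if (any(keep)) {
      pk <- par[, keep, drop = FALSE]
      vals <- vapply(seq_len(ncol(pk)), function(j)
        predict_fn(ivt_capping(pk[1, j], pk[2, j])), numeric(1))
      draws[got + seq_along(vals)] <- vals
      got <- got + length(vals)
    }
    if (n_rej > 50 * n_draws)
      stop("covariance places almost all mass outside the positive quadrant")
  }
  qs <- stats::quantile(draws, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  list(lower = qs[1], upper = qs[2], point = point, draws = draws,
       n_rejected = n_rej)
}
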