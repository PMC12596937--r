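# Trajectory and diagnostic figures (ggplot2).

#' Plot a simulation trajectory
#'
#' Faceted time courses of the main reactor variables. Bolus events appear
#' as the discontinuous jumps in the trajectories.
#'
#' @param object an `ivt_simulation`.
#' @param vars trajectory columns to facet.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ivt_simulation <- function(object,
                                    vars = c("rna_gL", "atp_mM", "gtp_mM",
                                             "pH", "effective_salt_mM",
                                             "sigma", "cfi", "rate_Ms"),
                                    ...) {
  tr <- tidyr::pivot_longer(object$trajectory[, c("time_s", vars)],
                            -"time_s", names_to = "variable")
  tr$variable <- factor(tr$variable, levels = vars)
  ggplot2::ggplot(tr, ggplot2::aes(.data$time_s / 60, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = NULL) +
    ggplot2::theme_bw()
}

#' Plot the rate-decline factor decomposition
#'
#' Lines for each multiplicative factor of the normalized rate (catalyst
#' dilution, salt, pH, NTP saturation) along with the normalized rate
#' itself.
#'
#' @param result an `ivt_simulation`.
#' @return a ggplot object.
#' @export
plot_rate_decomposition <- function(result) {
  d <- decompose_rate_decline(result)
  long <- tidyr::pivot_longer(
    d[, c("time_s", "f_catalyst", "f_salt", "f_ph", "f_ntp", "rate_ratio")],
    -"time_s", names_to = "factor")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s / 60, .data$value,
                                     color = .data$factor)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "factor (relative to t = 0)",
                  color = NULL) +
    ggplot2::theme_bw()
}

#' Plot a capping calibration fit
#'
#' Measured versus predicted cap fractions with measurement error bars.
#'
#' @param object an `ivt_cf_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ivt_cf_fit <- function(object, ...) {
  f <- object$fitted
  ggplot2::ggplot(f, ggplot2::aes(.data$cf_predicted, .data$cf_measured)) +
    ggplot2::geom_abline(linetype = 2, color = "grey50") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$cf_measured - .data$cf_sd,
                                        ymax = .data$cf_measured + .data$cf_sd),
                           width = 0) +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "predicted CF", y = "measured CF") +
    ggplot2::theme_bw()
}
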