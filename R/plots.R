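#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a log-binned duration histogram
#'
#' @param object A [log_histogram()].
#' @param fit Optional `mixture_fit` whose per-bin mixture mass is overlaid.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.log_histogram <- function(object, fit = NULL, ...) {
  d <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$log10_mid,
                                       y = .data$density)) +
    ggplot2::geom_col(width = d$log10_mid[2] - d$log10_mid[1],
                      fill = "grey70", colour = "grey40", linewidth = 0.2) +
    ggplot2::labs(x = expression(log[10] * "(unfolding duration / ms)"),
                  y = expression(N / N[0])) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    tf <- attr(object, "t_fold")
    amp <- fit$amplitudes
    if (!is.null(tf) && !is.na(tf) && tf %in% amp$t_fold) {
      amp <- amp[amp$t_fold == tf, ]
    } else {
      amp <- amp[amp$t_fold == amp$t_fold[1] | is.na(amp$t_fold), ]
    }
    curve <- tibble::tibble(
      log10_mid = d$log10_mid,
      mass = .bin_mass(d$bin_lo_ms, d$bin_hi_ms, amp$tau_ms, amp$amplitude)
    )
    p <- p + ggplot2::geom_line(data = curve,
                                ggplot2::aes(y = .data$mass),
                                colour = "firebrick", linewidth = 0.8)
  }
  p
}

#' Plot population kinetics
#'
#' Fractional population of each state against folding time (log axis),
#' optionally with master-equation prediction curves.
#'
#' @param object A long population tibble (`time_s`, `state`,
#'   `population`), e.g. from [solve_populations()] or
#'   [fractional_populations()] (rename `t_fold` to `time_s`).
#' @param predicted Optional second population tibble drawn as lines.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.population_kinetics <- function(object, predicted = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$time_s, y = .data$population,
                                    colour = .data$state)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~state, nrow = 1) +
    ggplot2::labs(x = "folding time (s)", y = "fractional population") +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
  if (!is.null(predicted)) {
    p <- p + ggplot2::geom_line(data = tibble::as_tibble(predicted))
  }
  p
}

#' Plot a rate fit
#'
#' Measured (buffer-corrected) populations as points with the fitted
#' master-equation curves, one facet per state.
#'
#' @param object A `rate_fit`.
#' @param n_curve Number of points on the prediction curve. Default 100.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rate_fit <- function(object, n_curve = 100, ...) {
  meas <- object$measured_corrected
  tmin <- max(min(meas$time_s[meas$time_s > 0]), 1e-3)
  tgrid <- 10^seq(log10(tmin), log10(max(meas$time_s)),
                  length.out = n_curve)
  pred <- solve_populations(object$scheme, tgrid)
  ggplot2::ggplot(meas, ggplot2::aes(x = .data$time_s,
                                     y = .data$population)) +
    ggplot2::geom_line(data = tibble::as_tibble(pred),
                       colour = "firebrick") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~state, nrow = 1) +
    ggplot2::labs(x = "folding time (s)", y = "fractional population") +
    ggplot2::theme_minimal()
}

#' Plot a current trace with its segments
#'
#' @param object A `current_trace`.
#' @param segments Optional segment tibble from [segment_levels()].
#' @param model A [trace_model()] used for the percent axis.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.current_trace <- function(object, segments = NULL,
                                   model = trace_model(), ...) {
  d <- tibble::tibble(
    time_ms = (seq_along(object$samples) - 1) /
      object$sampling_rate_hz * 1000,
    fraction = object$samples / model$open_current * 100
  )
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time_ms,
                                       y = .data$fraction)) +
    ggplot2::geom_line(linewidth = 0.2, colour = "grey30") +
    ggplot2::labs(x = "time (ms)", y = expression(I / I[0] ~ "(%)")) +
    ggplot2::theme_minimal()
  if (!is.null(segments)) {
    sg <- dplyr::mutate(
      segments,
      t0 = .data$start_index / object$sampling_rate_hz * 1000,
      t1 = .data$end_index / object$sampling_rate_hz * 1000)
    p <- p + ggplot2::geom_segment(
      data = sg,
      ggplot2::aes(x = .data$t0, xend = .data$t1,
                   y = .data$mean_fraction, yend = .data$mean_fraction),
      colour = "firebrick", linewidth = 0.9)
  }
  p
}
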