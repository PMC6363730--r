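# ggplot2 methods for the result objects.

#' Plot a simulated trajectory
#'
#' Faceted time courses of the model states (or the six observables).
#'
#' @param object A `pkpd_trajectory` from [simulate_pkpd()].
#' @param states Which states to show (default all 10); use
#'   `observables = TRUE` for the measured quantities instead.
#' @param observables Show the six observables rather than raw states.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pkpd_trajectory <- function(object, states = pkpd_states(),
                                     observables = FALSE, ...) {
  if (observables) {
    long <- observables(object)
    long$panel <- long$observable
  } else {
    long <- tidyr::pivot_longer(as_tibble(object),
                                dplyr::all_of(states),
                                names_to = "panel", values_to = "value")
    long$panel <- factor(long$panel, levels = states)
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = NULL)
}

#' Plot a visual predictive check
#'
#' Percentile envelopes of the simulated replicates as ribbons with the
#' observed percentiles overlaid, faceted by observable and group.
#'
#' @param object A `pkpd_vpc` from [vpc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pkpd_vpc <- function(object, ...) {
  df <- as_tibble(object)
  df$prob_lab <- paste0(100 * df$prob, "th percentile")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_lo,
                                      ymax = .data$sim_hi,
                                      fill = .data$prob_lab), alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed,
                                    colour = .data$prob_lab)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed,
                                     colour = .data$prob_lab), size = 0.8) +
    ggplot2::facet_grid(dvid ~ group, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = NULL, colour = "observed",
                  fill = "simulated envelope")
}

#' Plot normalized prediction distribution errors
#'
#' NPDE versus time with reference lines at 0 and +/- 1.96.
#'
#' @param object A `pkpd_npde` from [npde()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pkpd_npde <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$time, y = .data$npde)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_hline(yintercept = c(-1.96, 1.96), linetype = 3) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~dvid, scales = "free_x") +
    ggplot2::labs(x = "time (h)", y = "NPDE")
}
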