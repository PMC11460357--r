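# ggplot2 visualisations for the main result types.

#' Plot exposure counts by ideology category
#'
#' @param object An [tabulate_exposures()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.exposure_table <- function(object, ...) {
  ggplot2::ggplot(object$counts,
                  ggplot2::aes(x = .data$category, y = .data$n,
                               fill = .data$category)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~article_id, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Unique exposed users") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot cumulative receptive exposure over time
#'
#' Cumulative exposed and receptive user counts per article; receptive curves
#' weight each exposure by its category belief rate.
#'
#' @param object An [estimate_receptivity()] result with a time series.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.receptivity_estimate <- function(object, ...) {
  if (is.null(object$series)) {
    abort("No time series available; estimate from an exposure table with events.",
          class = "receptr_validation_error")
  }
  long <- object$series %>%
    tidyr::pivot_longer(c("cum_exposed", "cum_receptive"),
                        names_to = "measure", values_to = "users") %>%
    mutate(measure = dplyr::recode(.data$measure,
                                   cum_exposed = "exposed",
                                   cum_receptive = "receptive"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_bin, y = .data$users,
                                     colour = .data$measure)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~article_id, scales = "free_y") +
    ggplot2::labs(x = "Hours since first share", y = "Cumulative users",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot intervention effectiveness against deployment delay
#'
#' Mean percent reduction in receptive exposure with the central 90% band
#' across replicates and articles, per intervention type.
#'
#' @param object An [run_intervention_experiment()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.intervention_result <- function(object, ...) {
  agg <- summary(object)
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$t_int,
                                    y = .data$mean_pct_reduction,
                                    colour = .data$intervention,
                                    fill = .data$intervention)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q05, ymax = .data$q95),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression("Intervention delay" ~ t[int] ~ "(hours)"),
                  y = "Reduction in receptive exposure (%)",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
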