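#' Plot a competition trajectory
#'
#' Biomasses, toxins, and nutrient over time in one panel, with the
#' realised investments in a second facet.
#'
#' @param object A `toxwar_trajectory` tibble (from
#'   `simulate_competition(..., keep_trajectory = TRUE)$trajectory`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.toxwar_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(object, -"t", names_to = "variable",
                              values_to = "value")
  long$panel <- ifelse(long$variable %in% c("f_A", "f_B"),
                       "investment", "state")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                     colour = .data$variable)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (hr)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a pairwise invasibility grid
#'
#' Tiles the (resident, invader) plane by whether the invader's invasion
#' index exceeds one.
#'
#' @param object A `toxwar_pip` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.toxwar_pip <- function(object, ...) {
  d <- tidy(object)
  d$invades <- d$I_inv > 1
  ggplot2::ggplot(d, ggplot2::aes(x = .data$f_res, y = .data$f_inv,
                                  fill = .data$invades)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey20",
                                          `FALSE` = "grey90"),
                               na.value = "white") +
    ggplot2::labs(x = "resident f", y = "invader f",
                  fill = expression(I[inv] > 1)) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Plot genetic-algorithm convergence
#'
#' Mean parameter values of the fittest strategies per generation.
#'
#' @param object A `ga_history` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ga_history <- function(object, ...) {
  long <- tidyr::pivot_longer(object$summary,
                              c("f_initial", "f_induced", "threshold"),
                              names_to = "parameter", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$generation, y = .data$value,
                                     colour = .data$parameter)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = "mean of top strategies",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an invasion map
#'
#' Marks the `(f_initial, f_induced)` combinations where at least one
#' threshold lets the sensing strategy stably invade every constitutive
#' strategy.
#'
#' @param object A `toxwar_invasion_map` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.toxwar_invasion_map <- function(object, ...) {
  ggplot2::ggplot(object$map,
                  ggplot2::aes(x = .data$f_initial, y = .data$f_induced,
                               fill = .data$stable)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey90")) +
    ggplot2::labs(title = object$mode, fill = "stable invasion") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
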