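## ggplot2 visualization methods.

#' Plot concentration-time profiles of a simulation
#'
#' @param object A `pbpk_sim`.
#' @param compartments Compartments to show (default maternal plasma plus,
#'   when present, fetal venous blood and amniotic fluid).
#' @param log_y Log-scale the concentration axis.
#' @param observed Optional observed data (`time_h`, `value`, optional
#'   `observable`) overlaid as points.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pbpk_sim <- function(object, compartments = NULL, log_y = TRUE,
                              observed = NULL, ...) {
  compartments <- compartments %||%
    intersect(c("ven", "f_ven", "amniotic"), object$graph$state_names)
  df <- object$profiles |>
    dplyr::filter(.data$compartment %in% compartments,
                  .data$concentration > 0)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$concentration,
                                        color = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (h)", y = "Concentration (µg/mL)",
                  color = "Compartment") +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  if (!is.null(observed)) {
    obs <- observed
    if (is.null(obs$observable)) obs$observable <- compartments[1]
    p <- p + ggplot2::geom_point(
      data = obs,
      ggplot2::aes(.data$time_h, .data$value, color = .data$observable),
      inherit.aes = FALSE)
  }
  p
}

#' Plot population prediction bands
#'
#' @param object A `population_result`.
#' @param ... Unused.
#' @return A ggplot object with the median line and 5-95 / 25-75 ribbons
#'   per observable.
#' @export
autoplot.population_result <- function(object, ...) {
  df <- object$bands |> dplyr::filter(.data$p50 > 0)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$p50)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p5, ymax = .data$p95),
                         alpha = 0.2) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p25, ymax = .data$p75),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~observable, scales = "free_y") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Time (h)", y = "Concentration (µg/mL)") +
    ggplot2::theme_minimal()
}

#' Plot maternal and fetal physiology curves across gestation
#'
#' @param spec A [subject_spec()] giving the subject (GA ignored).
#' @param quantities Which curves to draw.
#' @return A ggplot object.
#' @export
plot_physiology_curves <- function(spec,
    quantities = c("weight_gain", "gfr", "hematocrit", "plasma_volume",
                   "fetal_weight", "amniotic_fluid_volume")) {
  ga <- seq(0, 42, by = 0.5)
  rows <- purrr::map_dfr(ga, function(g) {
    s <- subject_spec(spec$age, spec$weight, spec$height,
                      gestational_age = g, sex = "female")
    phys <- maternal_physiology(s)
    fet <- fetal_state(g)
    tibble::tibble(
      ga = g,
      weight_gain = phys$weight_gain,
      gfr = phys$gfr,
      hematocrit = phys$hematocrit,
      plasma_volume = phys$plasma_volume,
      fetal_weight = fet$fetal_weight,
      amniotic_fluid_volume = fet$amniotic_fluid_volume
    )
  })
  df <- rows |>
    tidyr::pivot_longer(-"ga", names_to = "quantity") |>
    dplyr::filter(.data$quantity %in% quantities)
  ggplot2::ggplot(df, ggplot2::aes(.data$ga, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "Gestational age (wk)", y = NULL) +
    ggplot2::theme_minimal()
}
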