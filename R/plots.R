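#' Plot water levels against marsh elevations
#'
#' Hourly stage for both areas with marsh-surface elevations as dashed lines
#' and pulse windows shaded, the standard diagnostic for whether the pulse
#' hydrograph floods the inflow marsh and obscures tidal periodicity.
#'
#' @param water_levels Water-level table.
#' @param pulses Optional pulse-window table to shade.
#' @return A ggplot object.
#' @export
plot_water_levels <- function(water_levels, pulses = NULL) {
  elev <- distinct(water_levels, area, marsh_elev_mm)
  p <- ggplot2::ggplot(water_levels,
                       ggplot2::aes(x = timestamp, y = stage_mm, colour = area))
  if (!is.null(pulses)) {
    p <- p + ggplot2::geom_rect(
      data = pulses, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start, xmax = .data$end, ymin = -Inf, ymax = Inf),
      fill = "grey85", alpha = 0.6)
  }
  p + ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(data = elev,
                        ggplot2::aes(yintercept = marsh_elev_mm, colour = area),
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Stage (mm, common datum)", colour = "Area") +
    ggplot2::theme_minimal()
}

#' @export
#' @method autoplot nekton_subsidy
autoplot.nekton_subsidy <- function(object, ...) {
  units <- c(density = "Density (ind m⁻²)",
             biomass = "Biomass (g DW m⁻²)",
             energy = "Energy (cal m⁻²)")
  df <- bind_rows(
    mutate(as_tibble(object), quantity = "inflow mean",
           value = inflow_mean, se = inflow_se),
    mutate(as_tibble(object), quantity = "pulse subsidy",
           value = subsidy, se = subsidy_se)) |>
    mutate(metric = factor(units[metric], levels = units))
  ggplot2::ggplot(df, ggplot2::aes(x = quantity, y = value, fill = quantity)) +
    ggplot2::geom_col(width = 0.6, show.legend = FALSE) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = value - se, ymax = value + se),
                           width = 0.2) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
#' @method autoplot pulse_study
autoplot.pulse_study <- function(object, ...) autoplot(object$subsidy, ...)

#' @export
#' @method autoplot allometry_fit
autoplot.allometry_fit <- function(object, wetdry = NULL, ...) {
  df <- as_tibble(object) |>
    mutate(intercept_plot = ifelse(intercept_dropped, 0, intercept))
  p <- ggplot2::ggplot()
  if (!is.null(wetdry)) {
    p <- p + ggplot2::geom_point(data = wetdry,
                                 ggplot2::aes(x = wet_g, y = dry_g),
                                 alpha = 0.3, size = 0.6)
  }
  p + ggplot2::geom_abline(data = df,
                           ggplot2::aes(slope = slope,
                                        intercept = .data$intercept_plot),
                           colour = "steelblue") +
    ggplot2::facet_wrap(~species, scales = "free") +
    ggplot2::labs(x = "Wet weight (g)", y = "Dry weight (g)") +
    ggplot2::theme_minimal()
}
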