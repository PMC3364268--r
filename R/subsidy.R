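metric_column <- function(metric) {
  switch(metric,
         density = "density_ind_m2",
         biomass = "biomass_gdw_m2",
         energy = "energy_cal_m2",
         unit = NA_character_,
         np_stop("unknown metric '", metric, "'"))
}

#' Per-pulse subsidized proportion of a standing-stock metric
#'
#' The fraction of a metric's total, over one pulse's samples, held by
#' pulse-subsidized samples: `X(subsidized) / X(total)`. Proportions are
#' ratios of totals (mass-weighted), not means of per-sample ratios. The
#' pseudo-metric `"unit"` scores 1 per sample, giving the subsidized share of
#' sample counts.
#'
#' @param metrics Per-sample metrics from [sample_metrics()].
#' @param classification Classification table from [classify_samples()]
#'   (provides `subsidized` and `pulse_id`).
#' @param metric One of `"density"`, `"biomass"`, `"energy"`, `"unit"`.
#' @return A tibble per pulse: `pulse_id`, `metric`, `proportion` (in [0, 1]),
#'   `subsidized_total`, `overall_total`, `n_subsidized`, `n_total`. A pulse
#'   whose overall total is zero gets proportion 0 with a warning.
#' @export
pulse_proportion <- function(metrics, classification, metric) {
  col <- metric_column(metric)
  require_columns(classification, c("sample_id", "pulse_id", "subsidized"),
                  "classification")
  require_columns(metrics, "sample_id", "metrics")
  df <- left_join(metrics, select(classification, "sample_id", "subsidized",
                                  pulse_id_cls = "pulse_id"),
                  by = "sample_id")
  np_assert(!anyNA(df$subsidized), "classification flag missing for sample(s): ",
            paste(head(df$sample_id[is.na(df$subsidized)]), collapse = ", "))
  if (!"pulse_id" %in% names(metrics)) df$pulse_id <- df$pulse_id_cls
  df$value <- if (is.na(col)) 1 else df[[col]]

  out <- df |>
    group_by(pulse_id) |>
    summarise(metric = metric,
              subsidized_total = sum(value[subsidized]),
              overall_total = sum(value),
              n_subsidized = sum(subsidized),
              n_total = n(), .groups = "drop") |>
    mutate(proportion = ifelse(overall_total > 0,
                               subsidized_total / overall_total, 0)) |>
    select("pulse_id", "metric", "proportion", "subsidized_total",
           "overall_total", "n_subsidized", "n_total")
  if (any(out$overall_total == 0)) {
    warn(paste0("overall total of '", metric, "' is zero for pulse(s): ",
                paste(out$pulse_id[out$overall_total == 0], collapse = ", "),
                "; proportion reported as 0"))
  }
  out
}

#' Per-pulse subsidized proportions for all three metrics
#'
#' @inheritParams pulse_proportion
#' @return Row-bound [pulse_proportion()] results for density, biomass, energy.
#' @export
pulse_proportions <- function(metrics, classification) {
  purrr::map_dfr(c("density", "biomass", "energy"),
                 ~ pulse_proportion(metrics, classification, .x))
}

#' Average subsidized proportions across pulses
#'
#' Mean of the per-pulse proportions, expressed in percent, with the standard
#' error over pulses (for two pulses this is `|p1 - p2| / 2`, in percent;
#' missing for a single pulse).
#'
#' @param props Output of [pulse_proportions()] (or [pulse_proportion()]).
#' @return A tibble per metric: `metric`, `proportion_pct`,
#'   `proportion_se_pct`, `n_pulses`.
#' @export
cross_pulse_mean <- function(props) {
  require_columns(props, c("pulse_id", "metric", "proportion"), "props")
  props |>
    group_by(metric) |>
    summarise(proportion_pct = 100 * mean(proportion),
              proportion_se_pct = 100 * se_mean(proportion),
              n_pulses = n(), .groups = "drop")
}

#' Mean standing stock in the inflow area
#'
#' Mean and standard error of each per-sample metric over all inflow samples,
#' both pulses pooled.
#'
#' @param metrics Per-sample metrics from [sample_metrics()].
#' @return A tibble per metric: `metric`, `inflow_mean`, `inflow_se`, `n`.
#' @export
inflow_means <- function(metrics) {
  metrics |>
    tidyr::pivot_longer(c("density_ind_m2", "biomass_gdw_m2", "energy_cal_m2"),
                        names_to = "metric", values_to = "value") |>
    mutate(metric = dplyr::recode(metric, density_ind_m2 = "density",
                                  biomass_gdw_m2 = "biomass",
                                  energy_cal_m2 = "energy")) |>
    group_by(metric) |>
    summarise(inflow_mean = mean(value), inflow_se = se_mean(value),
              n = n(), .groups = "drop")
}

#' Scale a subsidized proportion to an absolute subsidy estimate
#'
#' The subsidy is `Z = X * Y / 100`, where `X` is the mean inflow standing
#' stock (per m^2) and `Y` the cross-pulse subsidized percentage. Its standard
#' error combines the two relative errors under one of three rules:
#' `"quadrature"` (default), `Z * sqrt((X_err/X)^2 + (Y_err/Y)^2)`;
#' `"product"`, `Z * (X_err/X) * (Y_err/Y)`; or `"mean_only"`,
#' `Z * X_err / X` (only the standing-stock error scales). `Y = 0` gives
#' `Z = 0` with zero error.
#'
#' @param X,X_err Inflow mean and its SE (metric units per m^2, `X > 0`).
#' @param Y,Y_err Subsidized percentage and its SE (percent).
#' @param error_rule Error-combination rule, see above.
#' @return A one-row tibble: `X`, `X_err`, `Y`, `Y_err`, `Z`, `Z_err`.
#' @examples
#' subsidy_estimate(40.0, 7.2, 67.6, 17.1)
#' @export
subsidy_estimate <- function(X, X_err, Y, Y_err,
                             error_rule = c("quadrature", "product", "mean_only")) {
  error_rule <- match.arg(error_rule)
  np_assert(is.numeric(X) && length(X) == 1 && X > 0, "X must be a single positive value")
  np_assert(Y >= 0, "Y must be >= 0")
  Z <- X * Y / 100
  if (Y == 0) {
    Z_err <- 0
  } else {
    Z_err <- switch(error_rule,
                    quadrature = Z * sqrt((X_err / X)^2 + (Y_err / Y)^2),
                    product = Z * (X_err / X) * (Y_err / Y),
                    mean_only = Z * X_err / X)
  }
  tibble(X = X, X_err = X_err, Y = Y, Y_err = Y_err, Z = Z, Z_err = Z_err)
}

#' Assemble the subsidy summary table
#'
#' One row per metric, combining the pooled inflow mean, the cross-pulse
#' subsidized percentage and the scaled subsidy with propagated error — the
#' pipeline's headline result. Values are kept at full precision; rounding
#' happens only when printing/rendering.
#'
#' @inheritParams pulse_proportion
#' @inheritParams subsidy_estimate
#' @return A tibble of class `nekton_subsidy` with columns `metric`,
#'   `inflow_mean`, `inflow_se`, `proportion_pct`, `proportion_se_pct`,
#'   `subsidy`, `subsidy_se`.
#' @export
subsidy_table <- function(metrics, classification,
                          error_rule = c("quadrature", "product", "mean_only")) {
  error_rule <- match.arg(error_rule)
  props <- cross_pulse_mean(pulse_proportions(metrics, classification))
  means <- inflow_means(metrics)
  out <- inner_join(means, props, by = "metric") |>
    mutate(est = purrr::pmap(list(inflow_mean, inflow_se, proportion_pct,
                                  proportion_se_pct),
                             function(x, xe, y, ye)
                               subsidy_estimate(x, xe, y, ye, error_rule)),
           subsidy = purrr::map_dbl(.data$est, "Z"),
           subsidy_se = purrr::map_dbl(.data$est, "Z_err")) |>
    select("metric", "inflow_mean", "inflow_se", "proportion_pct",
           "proportion_se_pct", "subsidy", "subsidy_se") |>
    arrange(match(metric, c("density", "biomass", "energy")))
  attr(out, "error_rule") <- error_rule
  class(out) <- c("nekton_subsidy", class(out))
  out
}

#' @export
print.nekton_subsidy <- function(x, ...) {
  cat("Nekton standing-stock subsidy (error rule: ",
      attr(x, "error_rule") %||% "quadrature", ")\n", sep = "")
  units <- c(density = "ind m-2", biomass = "g DW m-2", energy = "cal m-2")
  df <- data.frame(
    metric = paste0(x$metric, " (", units[x$metric], ")"),
    inflow_mean = sprintf("%.1f (%.1f)", x$inflow_mean, x$inflow_se),
    subsidized_pct = sprintf("%.1f (%.1f)", x$proportion_pct, x$proportion_se_pct),
    subsidy = sprintf("%.1f (%.1f)", x$subsidy, x$subsidy_se))
  print(df, row.names = FALSE, right = FALSE)
  invisible(x)
}
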