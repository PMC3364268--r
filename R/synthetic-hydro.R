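#' Default pulse windows for the synthetic study
#'
#' Two managed flood-pulse release windows in spring 2005: February 14-28 and
#' March 12-28 (half-open, so the end day is the first day after each event).
#'
#' @return A [pulse_windows()] tibble with pulses `"feb"` and `"mar"`.
#' @export
default_pulse_windows <- function() {
  pulse_windows(c("feb", "mar"),
                c("2005-02-14 00:00:00", "2005-03-12 00:00:00"),
                c("2005-03-01 00:00:00", "2005-03-29 00:00:00"))
}

#' Hydrology configuration for the water-level generator
#'
#' Parameters of the two synthetic hourly stage series. The reference marsh
#' sees a tidal sinusoid plus a slowly varying meteorological component around
#' a mean stage below the marsh surface; the inflow marsh shares the
#' meteorological forcing and additionally receives a trapezoidal pulse
#' hydrograph that rides over the local stage and damps tidal periodicity
#' while the pulse runs. All stages are mm on a common vertical datum.
#'
#' @param window_start,window_end Simulation span (ISO strings or POSIXct;
#'   hourly readings are generated on `[start, end)`).
#' @param marsh_elevation_inflow,marsh_elevation_reference Marsh surface
#'   elevations (mm, common datum).
#' @param tidal_amplitude Tidal sinusoid amplitude (mm, >= 0).
#' @param tidal_period Tidal period (hours, > 0); default 12.42 (M2).
#' @param met_sd Standard deviation of the meteorological stage component (mm).
#' @param met_timescale e-folding timescale (hours) of the meteorological
#'   component (exponentially smoothed Gaussian, i.e. hourly AR(1)).
#' @param mean_stage_offset_reference Mean stage minus marsh elevation (mm);
#'   typically negative (marsh mostly dry without forcing). Applied to both
#'   areas relative to their own marsh elevation.
#' @param pulse_windows Pulse-release windows ([pulse_windows()] tibble).
#' @param pulse_plateau_depth Plateau depth of the pulse hydrograph above the
#'   inflow marsh surface (mm).
#' @param pulse_ramp_hours Linear ramp-up/ramp-down duration (hours).
#' @param tidal_damping_during_pulse Fraction in [0, 1] by which the tidal
#'   component is suppressed at full pulse strength (1 = fully obscured).
#' @param noise_sd Gauge noise standard deviation (mm).
#' @param seed Optional integer seed (generation is deterministic given it).
#' @return A list of class `hydro_config`.
#' @export
hydro_config <- function(window_start = "2005-02-01 00:00:00",
                         window_end = "2005-04-01 00:00:00",
                         marsh_elevation_inflow = 150,
                         marsh_elevation_reference = 120,
                         tidal_amplitude = 140,
                         tidal_period = 12.42,
                         met_sd = 70,
                         met_timescale = 48,
                         mean_stage_offset_reference = -150,
                         pulse_windows = default_pulse_windows(),
                         pulse_plateau_depth = 220,
                         pulse_ramp_hours = 120,
                         tidal_damping_during_pulse = 0.8,
                         noise_sd = 15,
                         seed = NULL) {
  cfg <- list(window_start = as_time(window_start), window_end = as_time(window_end),
              marsh_elevation_inflow = marsh_elevation_inflow,
              marsh_elevation_reference = marsh_elevation_reference,
              tidal_amplitude = tidal_amplitude, tidal_period = tidal_period,
              met_sd = met_sd, met_timescale = met_timescale,
              mean_stage_offset_reference = mean_stage_offset_reference,
              pulse_windows = pulse_windows,
              pulse_plateau_depth = pulse_plateau_depth,
              pulse_ramp_hours = pulse_ramp_hours,
              tidal_damping_during_pulse = tidal_damping_during_pulse,
              noise_sd = noise_sd, seed = seed)
  np_assert(cfg$window_start < cfg$window_end, "empty simulation window")
  np_assert(cfg$tidal_period > 0, "tidal_period must be positive")
  np_assert(cfg$tidal_amplitude >= 0, "tidal_amplitude must be >= 0")
  np_assert(cfg$tidal_damping_during_pulse >= 0 && cfg$tidal_damping_during_pulse <= 1,
            "tidal_damping_during_pulse must lie in [0, 1]")
  np_assert(all(c(cfg$met_sd, cfg$noise_sd) >= 0), "noise SDs must be >= 0")
  num <- unlist(cfg[c("marsh_elevation_inflow", "marsh_elevation_reference",
                      "tidal_amplitude", "met_sd", "mean_stage_offset_reference",
                      "pulse_plateau_depth", "noise_sd")])
  np_assert(all(is.finite(num)), "all stage quantities must be finite")
  if (nrow(pulse_windows) > 0) {
    np_assert(all(pulse_windows$start >= cfg$window_start &
                  pulse_windows$end <= cfg$window_end),
              "pulse windows must lie within the simulation window")
  }
  structure(cfg, class = "hydro_config")
}

# trapezoidal pulse weight in [0,1] over half-open windows
pulse_weight <- function(t, windows, ramp_hours) {
  w <- numeric(length(t))
  tn <- as.numeric(t)
  r <- ramp_hours * 3600
  for (i in seq_len(nrow(windows))) {
    s <- as.numeric(windows$start[i]); e <- as.numeric(windows$end[i])
    inside <- tn >= s & tn < e
    wi <- if (r <= 0) as.numeric(inside) else {
      pmax(0, pmin(1, (tn - s) / r, (e - tn) / r)) * inside
    }
    w <- pmax(w, wi)
  }
  w
}

#' Generate paired inflow/reference hourly water-level series
#'
#' Reference stage: marsh elevation + mean offset + tidal sinusoid +
#' exponentially smoothed meteorological process + gauge noise. Inflow stage:
#' the same meteorological forcing around its own marsh elevation, with the
#' tidal component damped by `tidal_damping_during_pulse` at full pulse
#' strength, and the non-tidal stage blended trapezoidally toward
#' `marsh elevation + pulse_plateau_depth` while the pulse runs (the riverine
#' head dominates the local stage, obscuring tidal periodicity). Generation is
#' deterministic for a fixed seed.
#'
#' @param cfg A [hydro_config()].
#' @param seed Integer seed; defaults to `cfg$seed`. `NULL` draws from the
#'   current RNG stream.
#' @return A tibble with `area` ("inflow"/"reference"), `timestamp`,
#'   `stage_mm`, `marsh_elev_mm`, hourly over `[window_start, window_end)`.
#' @examples
#' wl <- simulate_water_levels(hydro_config(seed = 1))
#' flooded_fraction(wl, default_pulse_windows())
#' @export
simulate_water_levels <- function(cfg, seed = cfg$seed) {
  np_assert(inherits(cfg, "hydro_config"), "cfg must come from hydro_config()")
  if (!is.null(seed)) set.seed(seed)
  tt <- seq(cfg$window_start, cfg$window_end, by = 3600)
  tt <- tt[tt < cfg$window_end]
  n <- length(tt)
  np_assert(n > 0, "empty simulation window")
  hours <- as.numeric(tt - tt[1], units = "hours")

  tide <- cfg$tidal_amplitude * sin(2 * pi * hours / cfg$tidal_period)

  # AR(1) with stationary sd met_sd and e-folding time met_timescale (hours)
  met <- numeric(n)
  if (cfg$met_sd > 0) {
    phi <- exp(-1 / cfg$met_timescale)
    met[1] <- rnorm(1, 0, cfg$met_sd)
    eps <- rnorm(n - 1, 0, cfg$met_sd * sqrt(1 - phi^2))
    for (i in seq_len(n - 1)) met[i + 1] <- phi * met[i] + eps[i]
  }
  noise_ref <- if (cfg$noise_sd > 0) rnorm(n, 0, cfg$noise_sd) else numeric(n)
  noise_in <- if (cfg$noise_sd > 0) rnorm(n, 0, cfg$noise_sd) else numeric(n)

  ref_stage <- cfg$marsh_elevation_reference + cfg$mean_stage_offset_reference +
    tide + met + noise_ref

  w <- pulse_weight(tt, cfg$pulse_windows, cfg$pulse_ramp_hours)
  in_base <- cfg$marsh_elevation_inflow + cfg$mean_stage_offset_reference + met
  in_plateau <- cfg$marsh_elevation_inflow + cfg$pulse_plateau_depth
  in_stage <- (1 - w) * in_base + w * in_plateau +
    tide * (1 - cfg$tidal_damping_during_pulse * w) + noise_in

  bind_rows(
    tibble(area = "inflow", timestamp = tt, stage_mm = in_stage,
           marsh_elev_mm = cfg$marsh_elevation_inflow),
    tibble(area = "reference", timestamp = tt, stage_mm = ref_stage,
           marsh_elev_mm = cfg$marsh_elevation_reference))
}
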