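# Builders for small deterministic fixtures used across test files.

t0 <- as.POSIXct("2005-02-14 00:00:00", tz = "UTC")

# hourly series for one area from a vector of signed depths (mm above marsh)
toy_series <- function(depths, area = "inflow", elev = 100,
                       start = t0) {
  tibble::tibble(
    area = area,
    timestamp = start + 3600 * (seq_along(depths) - 1),
    stage_mm = elev + depths,
    marsh_elev_mm = elev)
}

toy_levels <- function(inflow_depths, reference_depths, start = t0) {
  dplyr::bind_rows(toy_series(inflow_depths, "inflow", 100, start),
                   toy_series(reference_depths, "reference", 80, start))
}

toy_pulse <- function(n_hours, start = t0, id = "p1") {
  pulse_windows(id, start, start + 3600 * n_hours)
}

toy_samples <- function(times, pulse_id = "p1") {
  tibble::tibble(sample_id = sprintf("S%03d", seq_along(times)),
                 timestamp = times, pulse_id = pulse_id)
}

# minimal allometry/energy tables for metric tests
toy_models <- function(species = c("A", "B"), slope = c(0.2, 0.25),
                       intercept = c(NA, -0.01)) {
  m <- tibble::tibble(species = species, slope = slope, intercept = intercept,
                      intercept_dropped = is.na(intercept),
                      intercept_p = 0.5, r_squared = 0.9, n = 10L,
                      water_content_mean = 0.8, water_content_se = 0.01)
  class(m) <- c("allometry_fit", class(m))
  m
}

toy_energies <- function(species = c("A", "B"), energy = c(6000, 5500)) {
  tibble::tibble(species = species, mean_energy = energy, se = 50,
                 n_pellets = 3L)
}

# classification table built directly from flags
toy_flags <- function(sample_id, subsidized, pulse_id = "p1") {
  tibble::tibble(sample_id = sample_id, pulse_id = pulse_id,
                 subsidized = subsidized,
                 condition = ifelse(subsidized, "1", "none"),
                 inflow_daily_mean_depth_mm = NA_real_,
                 ref_flooded_at_sample = !subsidized,
                 ref_max_mean_depth_mm = NA_real_)
}

# deterministic hydrology: everything off except what a test switches on
quiet_hydro <- function(...) {
  hydro_config(tidal_amplitude = 0, met_sd = 0, noise_sd = 0,
               pulse_windows = pulse_windows(character(), as.POSIXct(character(), tz = "UTC"),
                                             as.POSIXct(character(), tz = "UTC")),
               ...)
}
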