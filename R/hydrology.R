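#' Define pulse windows
#'
#' A pulse window is the period of one managed flood-pulse release. Windows are
#' half-open: a reading or sample at time `t` belongs to the window when
#' `start <= t < end`.
#'
#' @param pulse_id Character labels, one per pulse.
#' @param start,end Window bounds (POSIXct or ISO-8601 strings, parsed as UTC).
#' @return A tibble with columns `pulse_id`, `start`, `end`.
#' @examples
#' pulse_windows(c("feb", "mar"),
#'               c("2005-02-14", "2005-03-12"),
#'               c("2005-03-01", "2005-03-29"))
#' @export
pulse_windows <- function(pulse_id, start, end) {
  start <- as_time(start)
  end <- as_time(end)
  np_assert(length(pulse_id) == length(start) && length(start) == length(end),
            "pulse_id, start and end must have equal length")
  np_assert(all(start < end), "every pulse window must have start < end")
  np_assert(!anyDuplicated(pulse_id), "pulse_id labels must be unique")
  tibble(pulse_id = as.character(pulse_id), start = start, end = end)
}

# restrict a water-level table to one area and check its contract
one_area_series <- function(water_levels, area_id) {
  require_columns(water_levels, c("area", "timestamp", "stage_mm", "marsh_elev_mm"),
                  "water_levels")
  wl <- water_levels[water_levels$area == area_id, , drop = FALSE]
  np_assert(nrow(wl) > 0, "no water-level readings for area '", area_id, "'")
  np_assert(!is.unsorted(wl$timestamp, strictly = TRUE),
            "timestamps must be strictly increasing within area '", area_id, "'")
  np_assert(all(is.finite(wl$stage_mm)), "stage must be finite in area '", area_id, "'")
  wl
}

#' Water depth over the marsh at given times
#'
#' Signed depth (stage minus marsh elevation, mm) at the gauge reading nearest
#' to each requested time. The marsh is flooded when the depth is strictly
#' positive. Ties halfway between two readings resolve to the earlier reading.
#'
#' @param water_levels Water-level table (`area`, `timestamp`, `stage_mm`,
#'   `marsh_elev_mm`).
#' @param at Times to evaluate (POSIXct or ISO-8601 strings).
#' @param area Area label to use; may be omitted when the table holds one area.
#' @return Numeric vector of signed depths (mm), one per element of `at`.
#' @export
depth_at <- function(water_levels, at, area = NULL) {
  if (is.null(area)) {
    areas <- unique(water_levels$area)
    np_assert(length(areas) == 1,
              "water_levels holds several areas; supply `area`")
    area <- areas
  }
  wl <- one_area_series(water_levels, area)
  at <- as_time(at)
  ts <- as.numeric(wl$timestamp)
  tq <- as.numeric(at)
  np_assert(all(tq >= ts[1] - 3600 & tq <= ts[length(ts)] + 3600),
            "requested time outside the span of area '", area, "' (±1 h)")
  idx <- findInterval(tq, ts, all.inside = TRUE)
  # choose nearer of the bracketing readings; ties go to the earlier one
  use_right <- (ts[idx + 1] - tq) < (tq - ts[idx])
  use_right[is.na(use_right)] <- FALSE
  pick <- idx + as.integer(use_right)
  pick <- pmin(pmax(pick, 1L), nrow(wl))
  wl$stage_mm[pick] - wl$marsh_elev_mm[pick]
}

window_rows <- function(wl, window_start, window_end) {
  wl$timestamp >= window_start & wl$timestamp < window_end
}

#' Fraction of time the marsh was flooded
#'
#' Percentage of hourly readings with depth strictly above the marsh surface,
#' per area and pulse window (windows are half-open `[start, end)`).
#'
#' @param water_levels Water-level table for one or more areas.
#' @param pulses Pulse-window table from [pulse_windows()].
#' @return A tibble with `area`, `pulse_id`, `n_readings`, `flooded_pct`.
#' @export
flooded_fraction <- function(water_levels, pulses) {
  require_columns(pulses, c("pulse_id", "start", "end"), "pulses")
  grid <- tidyr::expand_grid(area = unique(water_levels$area),
                             pulse_id = pulses$pulse_id)
  purrr::pmap_dfr(grid, function(area, pulse_id) {
    w <- pulses[pulses$pulse_id == pulse_id, ]
    wl <- one_area_series(water_levels, area)
    sel <- window_rows(wl, w$start, w$end)
    np_assert(any(sel), "no readings for area '", area, "' in pulse '", pulse_id, "'")
    depth <- wl$stage_mm[sel] - wl$marsh_elev_mm[sel]
    tibble(area = area, pulse_id = pulse_id, n_readings = sum(sel),
           flooded_pct = 100 * mean(depth > 0))
  })
}

#' Maximum daily mean depth of flooding in the reference area
#'
#' For each calendar day intersecting a pulse window, the mean depth over that
#' day's flooded readings only (depth > 0); the maximum of those daily means is
#' returned per pulse. `NA` when no reading in the window is flooded — a legal
#' result meaning the reference marsh never flooded during the pulse.
#'
#' @param water_levels Water-level table.
#' @param pulses Pulse-window table.
#' @param area Reference-area label (default `"reference"`).
#' @param day_mean `"flooded_only"` (default; mean over flooded readings) or
#'   `"all_floored"` (mean over all readings with depth floored at 0).
#' @return A tibble with `pulse_id`, `max_mean_depth_mm` (NA if never flooded).
#' @export
reference_max_mean_depth <- function(water_levels, pulses, area = "reference",
                                     day_mean = c("flooded_only", "all_floored")) {
  day_mean <- match.arg(day_mean)
  wl <- one_area_series(water_levels, area)
  purrr::pmap_dfr(pulses, function(pulse_id, start, end, ...) {
    sel <- window_rows(wl, start, end)
    np_assert(any(sel), "no readings for area '", area, "' in pulse '", pulse_id, "'")
    depth <- wl$stage_mm[sel] - wl$marsh_elev_mm[sel]
    day <- calendar_day(wl$timestamp[sel])
    daily <- tibble(day = day, depth = depth) |>
      group_by(day) |>
      summarise(mean_depth = if (day_mean == "flooded_only") {
        if (any(.data$depth > 0)) mean(.data$depth[.data$depth > 0]) else NA_real_
      } else {
        mean(pmax(.data$depth, 0))
      }, .groups = "drop")
    vals <- daily$mean_depth[!is.na(daily$mean_depth) & daily$mean_depth > 0]
    tibble(pulse_id = pulse_id,
           max_mean_depth_mm = if (length(vals)) max(vals) else NA_real_)
  })
}

# daily mean inflow depth on given calendar days, default: all readings floored at 0
inflow_daily_mean <- function(wl, days, day_mean = "all_floored") {
  all_days <- calendar_day(wl$timestamp)
  depth <- wl$stage_mm - wl$marsh_elev_mm
  vapply(days, function(d) {
    sel <- all_days == d
    np_assert(any(sel), "no inflow readings on day ", format(d))
    dd <- depth[sel]
    if (day_mean == "all_floored") mean(pmax(dd, 0))
    else if (any(dd > 0)) mean(dd[dd > 0]) else 0
  }, numeric(1))
}

#' Classify inflow drop samples as pulse-subsidized or not
#'
#' A sample is subsidized when flooding at its time and place is attributable
#' to the riverine pulse rather than tidal/meteorological forcing, under one
#' of two conditions: (1) the reference marsh was not flooded at the sample
#' time, or (2) the reference marsh was flooded, but the mean water level in
#' the inflow area on the sample's calendar day exceeded the maximum daily
#' mean depth of flooding in the reference area over the pulse window.
#'
#' "Reference not flooded" is evaluated at the hourly reading nearest the
#' sample time (depth <= 0 is dry; flooding is strict). The inflow daily mean
#' uses all readings of the sample's calendar day with depth floored at 0 per
#' reading; the reference daily means use flooded readings only. Both
#' conventions are switchable.
#'
#' @param samples Sample table with `sample_id`, `timestamp`, `pulse_id`.
#' @param water_levels Water-level table covering both areas.
#' @param pulses Pulse-window table.
#' @param inflow_area,reference_area Area labels in `water_levels`.
#' @param inflow_day_mean,ref_day_mean Daily-mean conventions (see above).
#' @param datum_offset Named numeric vector of per-area datum corrections (mm)
#'   added to the stage on read, e.g. `c(reference = 15)`. Default none.
#' @return A tibble with one row per sample: `sample_id`, `pulse_id`,
#'   `subsidized` (logical), `condition` (`"1"`, `"2"` or `"none"`),
#'   `inflow_daily_mean_depth_mm`, `ref_flooded_at_sample`,
#'   `ref_max_mean_depth_mm`.
#' @export
classify_samples <- function(samples, water_levels, pulses,
                             inflow_area = "inflow", reference_area = "reference",
                             inflow_day_mean = c("all_floored", "flooded_only"),
                             ref_day_mean = c("flooded_only", "all_floored"),
                             datum_offset = NULL) {
  inflow_day_mean <- match.arg(inflow_day_mean)
  ref_day_mean <- match.arg(ref_day_mean)
  require_columns(samples, c("sample_id", "timestamp", "pulse_id"), "samples")
  np_assert(nrow(samples) > 0, "no samples to classify")

  if (!is.null(datum_offset)) {
    for (a in names(datum_offset)) {
      hit <- water_levels$area == a
      water_levels$stage_mm[hit] <- water_levels$stage_mm[hit] + datum_offset[[a]]
      inform(paste0("applied datum offset ", datum_offset[[a]], " mm to area '", a, "'"))
    }
  }

  wl_in <- one_area_series(water_levels, inflow_area)
  samples <- mutate(samples, timestamp = as_time(timestamp))

  joined <- left_join(samples, pulses, by = "pulse_id")
  np_assert(!anyNA(joined$start), "sample pulse_id not present in `pulses`")
  inside <- joined$timestamp >= joined$start & joined$timestamp < joined$end
  np_assert(all(inside), "sample(s) fall outside their pulse window: ",
            paste(joined$sample_id[!inside], collapse = ", "))

  ref_max <- reference_max_mean_depth(water_levels, pulses, area = reference_area,
                                      day_mean = ref_day_mean)
  ref_depth <- depth_at(water_levels, joined$timestamp, area = reference_area)
  in_daily <- inflow_daily_mean(wl_in, calendar_day(joined$timestamp),
                                day_mean = inflow_day_mean)

  out <- joined |>
    mutate(ref_flooded_at_sample = ref_depth > 0,
           inflow_daily_mean_depth_mm = in_daily) |>
    left_join(ref_max, by = "pulse_id") |>
    rename(ref_max_mean_depth_mm = "max_mean_depth_mm")

  bad <- out$ref_flooded_at_sample & is.na(out$ref_max_mean_depth_mm)
  np_assert(!any(bad),
            "reference flooded at a sample but never flooded over its window; ",
            "series/window mismatch")

  out |>
    mutate(condition = dplyr::case_when(
             !ref_flooded_at_sample ~ "1",
             inflow_daily_mean_depth_mm > ref_max_mean_depth_mm ~ "2",
             TRUE ~ "none"),
           subsidized = condition %in% c("1", "2")) |>
    select("sample_id", "pulse_id", "subsidized", "condition",
           "inflow_daily_mean_depth_mm", "ref_flooded_at_sample",
           "ref_max_mean_depth_mm")
}
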