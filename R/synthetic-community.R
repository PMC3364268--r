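default_species_pool <- function() {
  sp <- tibble(
    species = c("Palaemonetes paludosus", "Heterandria formosa",
                "Gambusia affinis", "Lucania parva", "Poecilia latipinna",
                "Cyprinodon variegatus", "Menidia beryllina"),
    mean_density_when_flooded = c(19.8, 16.5, 6.2, 3.2, 0.68, 0.59, 2.5),
    density_dispersion = 0.5,
    length_log_mean = log(c(35, 15, 25, 35, 30, 30, 50)),
    length_log_sd = c(0.30, 0.25, 0.30, 0.25, 0.30, 0.25, 0.25),
    lengthweight_a = c(6.0e-6, 1.04e-5, 3.97e-6, 4.3e-6, 3.3e-6, 5.0e-6, 3.2e-6),
    lengthweight_b = c(2.8, 3.0, 3.0, 3.0, 3.0, 3.0, 3.0))
  mutate(sp, relative_abundance =
           mean_density_when_flooded / sum(mean_density_when_flooded),
         .after = "species")
}

default_env_ranges <- function() {
  list(salinity_psu = c(0.2, 0.7), do_ppm = c(1.0, 9.4),
       temp_c = c(10.5, 28.1), turbidity_ntu = c(0.8, 50.0))
}

#' Community configuration for the campaign generator
#'
#' Describes the resident nekton pool sampled by the 1 m^2 drop sampler. Six
#' dominant resident species make up ~95% of default abundance, plus one
#' rarer transient; per-species expected density (individuals m-2) applies at
#' flooded depths at or above `depth_scale_mm` and scales linearly with
#' shallower depth. Counts are negative-binomial (aggregated), individual
#' lengths lognormal, and pooled wet weight follows each species'
#' length-weight power law with multiplicative noise.
#'
#' @param species Per-species tibble with columns `species`,
#'   `relative_abundance` (fractions summing to 1), `mean_density_when_flooded`
#'   (ind m-2 at saturation depth), `density_dispersion` (negative-binomial
#'   size, > 0), `length_log_mean`, `length_log_sd` (log-mm),
#'   `lengthweight_a`, `lengthweight_b` (wet g = a * L^b, L in mm).
#' @param samples_per_day Drop samples attempted per sampling day.
#' @param depth_scale_mm Saturation depth (mm) above which expected density no
#'   longer increases.
#' @param wet_weight_cv Lognormal CV of the pooled wet-weight weighing.
#' @param env_ranges Named list of `c(min, max)` ranges for the four
#'   environmental variables recorded with each sample.
#' @param seed Optional integer seed.
#' @return A list of class `community_config`.
#' @export
community_config <- function(species = default_species_pool(),
                             samples_per_day = 5,
                             depth_scale_mm = 150,
                             wet_weight_cv = 0.05,
                             env_ranges = default_env_ranges(),
                             seed = NULL) {
  require_columns(species, c("species", "relative_abundance",
                             "mean_density_when_flooded", "density_dispersion",
                             "length_log_mean", "length_log_sd",
                             "lengthweight_a", "lengthweight_b"), "species")
  np_assert(abs(sum(species$relative_abundance) - 1) < 1e-6,
            "relative abundances must sum to 1")
  np_assert(all(species$mean_density_when_flooded >= 0), "densities must be >= 0")
  np_assert(all(species$density_dispersion > 0), "dispersion must be > 0")
  np_assert(samples_per_day >= 1, "samples_per_day must be >= 1")
  np_assert(depth_scale_mm > 0, "depth_scale_mm must be > 0")
  structure(list(species = species, samples_per_day = samples_per_day,
                 depth_scale_mm = depth_scale_mm, wet_weight_cv = wet_weight_cv,
                 env_ranges = env_ranges, seed = seed),
            class = "community_config")
}

#' True wet:dry allometry of the six dominant species
#'
#' Generator ground truth for the wet-to-dry conversion: per-species slope,
#' intercept (0 when the true relationship passes through the origin),
#' residual SD of the dry weighing, the number of individuals collected, and
#' the lognormal wet-weight distribution they are drawn from. Defaults give
#' near-linear structure with tissue water content around 0.78-0.81.
#'
#' @details Wet weights are lognormal truncated below at `ww_min_g` (animals
#'   below a species' weighable size range are not collected), and residual
#'   SDs are small enough relative to the smallest dry weights that the
#'   `(0, wet_g)` truncation of the dry weighing almost never binds, keeping
#'   the generated relationship linear over the sampled range.
#' @return A tibble with columns `species`, `true_slope`, `true_intercept`,
#'   `residual_sd`, `n_individuals`, `ww_log_mean`, `ww_log_sd`, `ww_min_g`.
#' @export
allometry_truth <- function() {
  tibble(
    species = dominant_species(),
    true_slope = c(0.190571, 0.205544, 0.206633, 0.241053, 0.230281, 0.215689),
    true_intercept = c(0, 0, -0.002934, -0.01548, -0.005112, -0.014876),
    residual_sd = c(0.0042, 0.0012, 0.0050, 0.0080, 0.0050, 0.0040),
    n_individuals = c(392L, 167L, 2193L, 80L, 164L, 39L),
    ww_log_mean = log(c(0.20, 0.06, 0.25, 0.35, 0.30, 0.50)),
    ww_log_sd = c(0.40, 0.40, 0.45, 0.40, 0.45, 0.40),
    ww_min_g = c(0.09, 0.025, 0.12, 0.20, 0.12, 0.25))
}

#' True pellet energy densities of the six dominant species
#'
#' Generator ground truth for bomb calorimetry: per-species mean energy
#' density (cal g-1 DW), between-pellet SD, and replicate pellet count.
#'
#' @return A tibble with `species`, `true_energy_density`, `pellet_sd`,
#'   `n_pellets`.
#' @export
calorimetry_truth <- function() {
  tibble(
    species = dominant_species(),
    true_energy_density = c(6141.85, 6626.12, 6294.70, 5790.55, 6435.60, 5421.80),
    pellet_sd = c(127.3, 10.6, 290.5, 408.7, 110.7, 17.3),
    n_pellets = c(8L, 2L, 36L, 4L, 5L, 3L))
}

#' Generate individual wet/dry weighings
#'
#' Draws `n_individuals` wet weights per species from its lognormal range and
#' dry weights from the true linear relationship plus Gaussian residual
#' noise, truncated to `(0, wet_g)` by resampling the residual (with a final
#' clamp if a draw keeps failing).
#'
#' @param truth An [allometry_truth()]-shaped tibble.
#' @param seed Optional integer seed.
#' @return A tibble with `species`, `individual_id`, `wet_g`, `dry_g`.
#' @export
simulate_wet_dry <- function(truth, seed = NULL) {
  require_columns(truth, c("species", "true_slope", "true_intercept",
                           "residual_sd", "n_individuals", "ww_log_mean",
                           "ww_log_sd"), "truth")
  np_assert(all(truth$n_individuals >= 3), "need n_individuals >= 3 per species")
  np_assert(all(truth$true_slope > 0 & truth$true_slope < 1),
            "true slopes must lie in (0, 1)")
  np_assert(all(truth$residual_sd >= 0), "residual_sd must be >= 0")
  if (is.null(truth[["ww_min_g"]])) truth$ww_min_g <- 0
  if (!is.null(seed)) set.seed(seed)
  purrr::pmap_dfr(truth, function(species, true_slope, true_intercept,
                                  residual_sd, n_individuals, ww_log_mean,
                                  ww_log_sd, ww_min_g, ...) {
    ww <- rlnorm(n_individuals, ww_log_mean, ww_log_sd)
    small <- which(ww < ww_min_g)
    while (length(small) > 0) {
      ww[small] <- rlnorm(length(small), ww_log_mean, ww_log_sd)
      small <- which(ww < ww_min_g)
    }
    mu <- true_intercept + true_slope * ww
    dw <- mu + rnorm(n_individuals, 0, residual_sd)
    bad <- which(dw <= 0 | dw >= ww)
    tries <- 0
    while (length(bad) > 0 && tries < 100) {
      dw[bad] <- mu[bad] + rnorm(length(bad), 0, residual_sd)
      bad <- which(dw <= 0 | dw >= ww)
      tries <- tries + 1
    }
    if (length(bad) > 0) dw[bad] <- pmin(pmax(mu[bad], 0.001 * ww[bad]), 0.999 * ww[bad])
    tibble(species = species,
           individual_id = sprintf("%s_%04d", abbreviate(species, 6), seq_len(n_individuals)),
           wet_g = ww, dry_g = dw)
  })
}

#' Generate calorimetry pellet replicates
#'
#' Replicate pellet energy densities are Normal around each species' true
#' value; non-positive draws (never seen at realistic SDs) are redrawn.
#'
#' @param truth A [calorimetry_truth()]-shaped tibble.
#' @param seed Optional integer seed.
#' @return A tibble with `species`, `replicate`, `cal_per_g_dw`.
#' @export
simulate_pellets <- function(truth, seed = NULL) {
  require_columns(truth, c("species", "true_energy_density", "pellet_sd",
                           "n_pellets"), "truth")
  np_assert(all(truth$true_energy_density > 0), "energy densities must be > 0")
  np_assert(all(truth$n_pellets >= 1), "need n_pellets >= 1")
  if (!is.null(seed)) set.seed(seed)
  purrr::pmap_dfr(truth, function(species, true_energy_density, pellet_sd,
                                  n_pellets, ...) {
    e <- rnorm(n_pellets, true_energy_density, pellet_sd)
    while (any(e <= 0)) e[e <= 0] <- rnorm(sum(e <= 0), true_energy_density, pellet_sd)
    tibble(species = species, replicate = seq_len(n_pellets), cal_per_g_dw = e)
  })
}

#' Generate a drop-sampler campaign over the pulse windows
#'
#' For each calendar day of each pulse window, up to `samples_per_day`
#' sampling times are drawn uniformly (without replacement) from that day's
#' flooded hours in the inflow area; a day with a dry marsh yields no samples
#' (a window with none at all raises a warning). Per sample and species,
#' counts are negative-binomial with mean
#' `mean_density_when_flooded * min(depth / depth_scale_mm, 1)`, individual
#' lengths lognormal, pooled wet weight `sum(a * L^b)` with multiplicative
#' lognormal noise, and environmental variables uniform within their
#' configured ranges. Ground-truth subsidized flags are attached via
#' [true_subsidy_flags()], an implementation of the classification rule
#' independent of [classify_samples()].
#'
#' @param community A [community_config()].
#' @param water_levels Water-level table covering both areas (e.g. from
#'   [simulate_water_levels()]).
#' @param pulses Pulse-window table.
#' @param seed Optional integer seed; defaults to `community$seed`.
#' @return A list with tibbles `samples` (`sample_id`, `area`, `timestamp`,
#'   `pulse_id`, environmental variables, `depth_mm_mean`), `catch`
#'   (`sample_id`, `species`, `count`, `wet_weight_g`; rows only for non-zero
#'   catches) and `truth` (`sample_id`, `true_subsidized`, `true_condition`).
#' @export
simulate_campaign <- function(community, water_levels, pulses,
                              seed = community$seed) {
  np_assert(inherits(community, "community_config"),
            "community must come from community_config()")
  if (!is.null(seed)) set.seed(seed)
  wl_in <- one_area_series(water_levels, "inflow")
  np_assert(all(pulses$start >= min(wl_in$timestamp) &
                pulses$end <= max(wl_in$timestamp) + 3600),
            "water levels must cover the pulse windows")
  depth <- wl_in$stage_mm - wl_in$marsh_elev_mm
  day <- calendar_day(wl_in$timestamp)

  picks <- list()
  for (i in seq_len(nrow(pulses))) {
    sel <- which(window_rows(wl_in, pulses$start[i], pulses$end[i]) & depth > 0)
    if (length(sel) == 0) {
      warn(paste0("inflow marsh never flooded during pulse '",
                  pulses$pulse_id[i], "'; no samples generated"))
      next
    }
    for (d in split(sel, day[sel])) {
      k <- min(community$samples_per_day, length(d))
      idx <- if (length(d) == 1) d else sample(d, k)
      picks[[length(picks) + 1]] <- tibble(row = idx, pulse_id = pulses$pulse_id[i])
    }
  }
  if (length(picks) == 0) {
    empty <- tibble(sample_id = character(), area = character(),
                    timestamp = as_time(character()), pulse_id = character(),
                    salinity_psu = numeric(), do_ppm = numeric(),
                    temp_c = numeric(), turbidity_ntu = numeric(),
                    depth_mm_mean = numeric())
    return(list(samples = empty,
                catch = tibble(sample_id = character(), species = character(),
                               count = integer(), wet_weight_g = numeric()),
                truth = tibble(sample_id = character(),
                               true_subsidized = logical(),
                               true_condition = character())))
  }
  picks <- bind_rows(picks) |> arrange(row)
  er <- community$env_ranges
  n_s <- nrow(picks)
  samples <- tibble(
    sample_id = sprintf("S%04d", seq_len(n_s)),
    area = "inflow",
    timestamp = wl_in$timestamp[picks$row],
    pulse_id = picks$pulse_id,
    salinity_psu = runif(n_s, er$salinity_psu[1], er$salinity_psu[2]),
    do_ppm = runif(n_s, er$do_ppm[1], er$do_ppm[2]),
    temp_c = runif(n_s, er$temp_c[1], er$temp_c[2]),
    turbidity_ntu = runif(n_s, er$turbidity_ntu[1], er$turbidity_ntu[2]),
    depth_mm_mean = pmax(depth[picks$row] + rnorm(n_s, 0, 5), 1))

  sp <- community$species
  catch <- purrr::map_dfr(seq_len(n_s), function(i) {
    d <- depth[picks$row[i]]
    mu <- sp$mean_density_when_flooded * min(d / community$depth_scale_mm, 1)
    counts <- rnbinom(nrow(sp), size = sp$density_dispersion, mu = mu)
    keep <- which(counts > 0)
    if (length(keep) == 0) return(NULL)
    purrr::map_dfr(keep, function(j) {
      len <- rlnorm(counts[j], sp$length_log_mean[j], sp$length_log_sd[j])
      ww <- sum(sp$lengthweight_a[j] * len^sp$lengthweight_b[j])
      ww <- ww * rlnorm(1, 0, community$wet_weight_cv)
      tibble(sample_id = samples$sample_id[i], species = sp$species[j],
             count = counts[j], wet_weight_g = ww)
    })
  })
  if (nrow(catch) == 0) {
    catch <- tibble(sample_id = character(), species = character(),
                    count = integer(), wet_weight_g = numeric())
  }

  truth <- true_subsidy_flags(samples, water_levels, pulses)
  list(samples = samples, catch = catch, truth = truth)
}

#' Ground-truth subsidy flags (independent rule implementation)
#'
#' Applies the two-condition subsidized-sample rule with a separate base-R
#' implementation (nearest-reading lookup via `which.min`, daily means via
#' `tapply`) that shares no code with [classify_samples()], so agreement
#' between the two is a genuine oracle check for the pipeline classifier.
#'
#' @param samples Sample table (`sample_id`, `timestamp`, `pulse_id`).
#' @param water_levels Water-level table covering both areas.
#' @param pulses Pulse-window table.
#' @return A tibble with `sample_id`, `true_subsidized`, `true_condition`.
#' @export
true_subsidy_flags <- function(samples, water_levels, pulses) {
  wl_in <- water_levels[water_levels$area == "inflow", , drop = FALSE]
  wl_ref <- water_levels[water_levels$area == "reference", , drop = FALSE]
  t_in <- as.numeric(wl_in$timestamp)
  t_ref <- as.numeric(wl_ref$timestamp)
  d_in <- wl_in$stage_mm - wl_in$marsh_elev_mm
  d_ref <- wl_ref$stage_mm - wl_ref$marsh_elev_mm
  day_in <- as.Date(wl_in$timestamp, tz = time_zone(wl_in$timestamp))
  day_ref <- as.Date(wl_ref$timestamp, tz = time_zone(wl_ref$timestamp))

  # per-pulse max of daily means over flooded reference readings
  ref_max <- numeric(nrow(pulses))
  names(ref_max) <- pulses$pulse_id
  for (i in seq_len(nrow(pulses))) {
    inw <- wl_ref$timestamp >= pulses$start[i] & wl_ref$timestamp < pulses$end[i]
    fl <- inw & d_ref > 0
    ref_max[i] <- if (!any(fl)) NA_real_ else
      max(tapply(d_ref[fl], as.character(day_ref[fl]), mean))
  }

  n <- nrow(samples)
  cond <- character(n)
  ts <- as.numeric(as_time(samples$timestamp))
  for (i in seq_len(n)) {
    j <- which.min(abs(t_ref - ts[i]))          # first (earlier) wins ties
    if (d_ref[j] <= 0) {
      cond[i] <- "1"
    } else {
      sd <- day_in == as.Date(as_time(samples$timestamp[i]),
                              tz = time_zone(wl_in$timestamp))
      daily_mean <- mean(pmax(d_in[sd], 0))
      rm <- ref_max[[samples$pulse_id[i]]]
      cond[i] <- if (!is.na(rm) && daily_mean > rm) "2" else "none"
    }
  }
  tibble(sample_id = samples$sample_id, true_subsidized = cond %in% c("1", "2"),
         true_condition = cond)
}
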