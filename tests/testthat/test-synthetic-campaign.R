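flat_flooded_hydro <- function(days, depth = 300) {
  start <- "2005-02-01 00:00:00"
  end <- as.POSIXct(start, tz = "UTC") + days * 86400
  hydro_config(window_start = start, window_end = end,
               tidal_amplitude = 0, met_sd = 0, noise_sd = 0,
               pulse_windows = pulse_windows("p1", start, end),
               pulse_plateau_depth = depth, pulse_ramp_hours = 0)
}

one_species_community <- function(mu, size = 5, spd = 20) {
  sp <- tibble::tibble(species = "Gambusia affinis", relative_abundance = 1,
                       mean_density_when_flooded = mu, density_dispersion = size,
                       length_log_mean = log(25), length_log_sd = 0.3,
                       lengthweight_a = 4e-6, lengthweight_b = 3)
  community_config(species = sp, samples_per_day = spd)
}

test_that("zero configured density yields an all-empty catch", {
  hy <- flat_flooded_hydro(3)
  wl <- simulate_water_levels(hy, seed = 1)
  camp <- simulate_campaign(one_species_community(0), wl, hy$pulse_windows, seed = 1)
  expect_gt(nrow(camp$samples), 0)
  expect_equal(nrow(camp$catch), 0)
})

test_that("catch counts match negative-binomial moments at fixed depth", {
  hy <- flat_flooded_hydro(50) # 50 fully flooded days x 20 samples = 1000 samples
  wl <- simulate_water_levels(hy, seed = 2)
  mu <- 12
  size <- 5
  camp <- simulate_campaign(one_species_community(mu, size), wl,
                            hy$pulse_windows, seed = 2)
  expect_equal(nrow(camp$samples), 1000)
  counts <- dplyr::left_join(camp$samples["sample_id"],
                             camp$catch[c("sample_id", "count")],
                             by = "sample_id")$count
  counts[is.na(counts)] <- 0
  # depth 300 >= saturation, so the mean is mu; NB variance mu + mu^2/size
  se <- sqrt(mu + mu^2 / size) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - mu), 3 * se)
})

test_that("the default campaign resembles the field effort", {
  d <- simulate_pulse_study(seed = 4)
  n_by_pulse <- table(d$samples$pulse_id)
  expect_gt(n_by_pulse[["feb"]], 40)
  expect_lt(n_by_pulse[["feb"]], 100)
  expect_gt(n_by_pulse[["mar"]], 45)
  expect_lt(n_by_pulse[["mar"]], 110)
  # six dominant residents carry ~95% of configured abundance
  tot <- sum(d$catch$count)
  dom <- sum(d$catch$count[d$catch$species %in% dominant_species()])
  expect_gt(dom / tot, 0.9)
  # ground truth flags exist for every sample
  expect_setequal(d$truth$sample_id, d$samples$sample_id)
  # sampler-recorded depths are positive (samples only at flooded hours)
  expect_true(all(d$samples$depth_mm_mean > 0))
})

test_that("a marsh that never floods yields a warning and zero samples", {
  hy <- hydro_config(tidal_amplitude = 0, met_sd = 0, noise_sd = 0,
                     mean_stage_offset_reference = -200,
                     pulse_windows = pulse_windows("p1", "2005-02-14", "2005-02-20"),
                     pulse_plateau_depth = -50, pulse_ramp_hours = 0)
  wl <- simulate_water_levels(hy, seed = 1)
  expect_warning(camp <- simulate_campaign(community_config(), wl,
                                           hy$pulse_windows, seed = 1),
                 "never flooded")
  expect_equal(nrow(camp$samples), 0)
})

test_that("wet/dry generation honours the noise-free line and the DW < WW contract", {
  truth0 <- tibble::tibble(species = "sp", true_slope = 0.2, true_intercept = 0,
                           residual_sd = 0, n_individuals = 10L,
                           ww_log_mean = 0, ww_log_sd = 0) # WW = 1 exactly
  wd0 <- simulate_wet_dry(truth0, seed = 1)
  expect_equal(wd0$wet_g, rep(1, 10))
  expect_equal(wd0$dry_g, rep(0.2, 10))

  for (s in 1:5) {
    wd <- simulate_wet_dry(allometry_truth(), seed = s)
    expect_true(all(wd$dry_g > 0 & wd$dry_g < wd$wet_g))
  }
})

test_that("regression on generated data recovers the configured truth", {
  truth <- allometry_truth()
  gam <- truth[truth$species == "Gambusia affinis", ]
  covered <- 0
  reps <- 40
  for (s in seq_len(reps)) {
    wd <- simulate_wet_dry(gam, seed = 1000 + s)
    f <- lm(dry_g ~ wet_g, data = wd)
    ci <- stats::confint(f, "wet_g", level = 0.95)
    covered <- covered + (gam$true_slope >= ci[1] && gam$true_slope <= ci[2])
  }
  # ~95% coverage; allow binomial slack at 40 replicates
  expect_gte(covered, 33)

  # Poecilia's negative intercept is strong enough to be retained
  poe <- truth[truth$species == "Poecilia latipinna", ]
  retained <- 0
  slopes <- numeric(20)
  for (s in 1:20) {
    wd <- simulate_wet_dry(poe, seed = 2000 + s)
    f <- fit_wet_dry(wd)
    retained <- retained + !f$intercept_dropped
    slopes[s] <- f$slope
  }
  expect_gte(retained, 16)
  expect_lt(abs(mean(slopes) - poe$true_slope), 0.01)
})

test_that("pellet generation matches its configured moments", {
  truth1 <- tibble::tibble(species = "sp", true_energy_density = 6141.85,
                           pellet_sd = 0, n_pellets = 5L)
  p0 <- simulate_pellets(truth1, seed = 1)
  expect_equal(p0$cal_per_g_dw, rep(6141.85, 5))

  truth2 <- tibble::tibble(species = "sp", true_energy_density = 6141.85,
                           pellet_sd = 127.3, n_pellets = 500L)
  p <- simulate_pellets(truth2, seed = 2)
  expect_lt(abs(mean(p$cal_per_g_dw) - 6141.85), 3 * 127.3 / sqrt(500))

  truth3 <- tibble::tibble(species = "sp", true_energy_density = 5421.80,
                           pellet_sd = 10, n_pellets = 1L)
  p1 <- simulate_pellets(truth3, seed = 3)
  expect_equal(nrow(p1), 1)
  expect_true(is.na(mean_energy_density(p1)$se))
})

test_that("all four generators are bit-reproducible under a fixed seed", {
  hy <- hydro_config(seed = 11)
  expect_identical(simulate_water_levels(hy), simulate_water_levels(hy))
  wl <- simulate_water_levels(hy)
  co <- community_config(seed = 12)
  expect_identical(simulate_campaign(co, wl, hy$pulse_windows),
                   simulate_campaign(co, wl, hy$pulse_windows))
  expect_identical(simulate_wet_dry(allometry_truth(), seed = 13),
                   simulate_wet_dry(allometry_truth(), seed = 13))
  expect_identical(simulate_pellets(calorimetry_truth(), seed = 14),
                   simulate_pellets(calorimetry_truth(), seed = 14))
})
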