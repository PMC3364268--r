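#' The six dominant resident nekton species
#'
#' The resident species that dominate drop-sampler catches on the flooded
#' marsh (riverine grass shrimp, least killifish, mosquitofish, rainwater
#' killifish, sailfin molly, sheepshead minnow). Standing-stock metrics are
#' restricted to this set by default so density, biomass and energy density
#' describe the same assemblage.
#'
#' @return Character vector of six species names.
#' @export
dominant_species <- function() {
  c("Palaemonetes paludosus", "Heterandria formosa", "Gambusia affinis",
    "Lucania parva", "Poecilia latipinna", "Cyprinodon variegatus")
}

#' Species energy density from pellet calorimetry
#'
#' Arithmetic mean and standard error, over bomb-calorimetry pellet
#' replicates, of tissue energy density (cal per g dry weight), one row per
#' species. All pellets of a species are pooled across collection dates.
#'
#' @param pellets Tibble with `species`, `replicate`, `cal_per_g_dw` (> 0).
#' @return A tibble with `species`, `mean_energy` (cal g-1 DW), `se` (NA when
#'   a species has a single pellet), `n_pellets`.
#' @export
mean_energy_density <- function(pellets) {
  require_columns(pellets, c("species", "cal_per_g_dw"), "pellets")
  np_assert(nrow(pellets) > 0, "no pellet records")
  np_assert(all(is.finite(pellets$cal_per_g_dw) & pellets$cal_per_g_dw > 0),
            "pellet energy densities must be positive and finite")
  pellets |>
    group_by(species) |>
    summarise(mean_energy = mean(cal_per_g_dw),
              se = se_mean(cal_per_g_dw),
              n_pellets = n(), .groups = "drop")
}

check_species_coverage <- function(present, models, energies) {
  miss_m <- setdiff(present, models$species)
  np_assert(length(miss_m) == 0,
            "no allometric model for included species: ", paste(miss_m, collapse = ", "))
  miss_e <- setdiff(present, energies$species)
  np_assert(length(miss_e) == 0,
            "no energy density for included species: ", paste(miss_e, collapse = ", "))
}

#' Per-sample standing-stock metrics
#'
#' For each 1 m^2 drop sample: nekton density (individuals m-2, the summed
#' counts), dry-weight biomass (g DW m-2, pooled wet weights converted through
#' the allometric models), and standing-stock energy density (cal m-2, each
#' species' dry weight times its energy density, summed). Only
#' `included_species` contribute, to all three metrics alike; samples with no
#' included catch score zero. Supplying `samples` guarantees a row for every
#' sample (including empty ones) and carries `pulse_id` through.
#'
#' @param catch Catch table: `sample_id`, `species`, `count`, `wet_weight_g`.
#' @param models An `allometry_fit` table from [fit_wet_dry()].
#' @param energies Species energy densities from [mean_energy_density()].
#' @param included_species Species to count; defaults to [dominant_species()].
#' @param samples Optional sample table (`sample_id`, `pulse_id`) so that
#'   samples absent from `catch` appear with zero metrics.
#' @return A tibble with `sample_id` (+ `pulse_id` when `samples` is given),
#'   `density_ind_m2`, `biomass_gdw_m2`, `energy_cal_m2`.
#' @export
sample_metrics <- function(catch, models, energies,
                           included_species = dominant_species(),
                           samples = NULL) {
  long <- sample_species_metrics(catch, models, energies, included_species)
  totals <- long |>
    group_by(sample_id) |>
    summarise(density_ind_m2 = sum(density_ind_m2),
              biomass_gdw_m2 = sum(biomass_gdw_m2),
              energy_cal_m2 = sum(energy_cal_m2), .groups = "drop")
  if (!is.null(samples)) {
    require_columns(samples, "sample_id", "samples")
    keep <- intersect(c("sample_id", "pulse_id"), names(samples))
    totals <- samples[, keep, drop = FALSE] |>
      left_join(totals, by = "sample_id") |>
      mutate(across(c(density_ind_m2, biomass_gdw_m2, energy_cal_m2),
                    ~ tidyr::replace_na(.x, 0)))
  }
  totals
}

#' Per-sample, per-species standing-stock metrics
#'
#' The species-resolved breakdown behind [sample_metrics()]; totals are exact
#' sums of these rows.
#'
#' @inheritParams sample_metrics
#' @return A tibble with `sample_id`, `species`, `density_ind_m2`,
#'   `biomass_gdw_m2`, `energy_cal_m2`.
#' @export
sample_species_metrics <- function(catch, models, energies,
                                   included_species = dominant_species()) {
  require_columns(catch, c("sample_id", "species", "count", "wet_weight_g"), "catch")
  kept <- filter(catch, species %in% included_species)
  check_species_coverage(unique(kept$species), models, energies)
  kept |>
    add_dry_weight(models) |>
    left_join(select(energies, "species", "mean_energy"), by = "species") |>
    group_by(sample_id, species) |>
    summarise(density_ind_m2 = sum(count),
              biomass_gdw_m2 = sum(.data$dry_weight_g),
              energy_cal_m2 = sum(.data$dry_weight_g * mean_energy),
              .groups = "drop")
}
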