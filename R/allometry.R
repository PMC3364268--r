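#' Fit per-species wet-weight to dry-weight conversions
#'
#' Ordinary least squares `DW = b0 + b1 * WW` per species, fitted on
#' individually weighed animals. The intercept is kept only when its two-sided
#' t-test rejects `b0 = 0` at level `alpha`; otherwise the model is refitted
#' through the origin and flagged `intercept_dropped`. For through-origin fits
#' the reported r-squared uses the uncentred total sum of squares (the
#' `summary.lm` convention for no-intercept models). Mean tissue water content
#' `1 - DW/WW` and its standard error over individuals are reported alongside.
#'
#' @param wetdry Tibble of individual weighings: `species`, `wet_g`, `dry_g`
#'   (0 < dry_g < wet_g).
#' @param alpha Significance level for the intercept gate, in (0, 0.5].
#' @return A tibble of class `allometry_fit`, one row per species: `species`,
#'   `slope`, `intercept` (NA when dropped), `intercept_dropped`,
#'   `intercept_p`, `r_squared`, `n`, `water_content_mean`, `water_content_se`.
#' @examples
#' wd <- tibble::tibble(species = "sp", wet_g = 1:5,
#'                      dry_g = 0.2 * (1:5) + c(0.01, -0.02, 0.02, -0.01, 0.02))
#' fit_wet_dry(wd)
#' @export
fit_wet_dry <- function(wetdry, alpha = 0.05) {
  require_columns(wetdry, c("species", "wet_g", "dry_g"), "wetdry")
  np_assert(is.numeric(alpha) && length(alpha) == 1 && alpha > 0 && alpha <= 0.5,
            "alpha must be a single value in (0, 0.5]")
  np_assert(all(wetdry$wet_g > 0), "wet weights must be positive")
  np_assert(all(wetdry$dry_g > 0 & wetdry$dry_g < wetdry$wet_g),
            "dry weights must satisfy 0 < dry_g < wet_g")

  out <- wetdry |>
    group_by(species) |>
    dplyr::group_modify(~ fit_one_species(.x, .y$species, alpha)) |>
    ungroup()
  class(out) <- c("allometry_fit", class(out))
  out
}

fit_one_species <- function(df, sp, alpha) {
  np_assert(nrow(df) >= 3, "species '", sp, "': need at least 3 wet/dry records")
  np_assert(stats::var(df$wet_g) > 0, "species '", sp, "': wet weights have zero variance")
  full <- lm(dry_g ~ wet_g, data = df)
  p_int <- summary(full)$coefficients["(Intercept)", "Pr(>|t|)"]
  # a perfect (zero-residual) fit yields an undefined t-test: keep no intercept
  if (!is.finite(p_int) || p_int >= alpha) {
    origin <- lm(dry_g ~ wet_g - 1, data = df)
    slope <- unname(coef(origin)[["wet_g"]])
    intercept <- NA_real_
    dropped <- TRUE
    r2 <- summary(origin)$r.squared
  } else {
    slope <- unname(coef(full)[["wet_g"]])
    intercept <- unname(coef(full)[["(Intercept)"]])
    dropped <- FALSE
    r2 <- summary(full)$r.squared
  }
  if (slope <= 0 || slope >= 1) {
    warn(paste0("species '", sp, "': fitted slope ", signif(slope, 4),
                " outside (0, 1); check the input data"))
  }
  wc <- 1 - df$dry_g / df$wet_g
  tibble(slope = slope, intercept = intercept, intercept_dropped = dropped,
         intercept_p = p_int, r_squared = r2, n = nrow(df),
         water_content_mean = mean(wc), water_content_se = se_mean(wc))
}

#' @export
#' @method tidy allometry_fit
tidy.allometry_fit <- function(x, ...) {
  as_tibble(x)[, c("species", "slope", "intercept", "intercept_dropped",
                   "r_squared", "n")]
}

#' @export
#' @method glance allometry_fit
glance.allometry_fit <- function(x, ...) {
  tibble(n_species = nrow(x), n_individuals = sum(x$n),
         n_intercept_dropped = sum(x$intercept_dropped),
         min_r_squared = min(x$r_squared), max_r_squared = max(x$r_squared))
}

#' Convert pooled wet weights to dry weight
#'
#' Applies the per-species conversion to a pooled weighing of `count`
#' individuals. The regression is fitted on individuals, so for models with a
#' retained intercept the intercept contributes once per individual:
#' `DW = count * intercept + slope * wet_g`; through-origin models give
#' `slope * wet_g` regardless of count. Predictions are floored at zero (a
#' negative value is possible for tiny weights with a negative intercept) with
#' a warning.
#'
#' @param models An `allometry_fit` table from [fit_wet_dry()].
#' @param species Character vector of species labels.
#' @param wet_g Pooled wet weights (g, >= 0).
#' @param count Individuals in each pooled weighing (>= 0).
#' @return Numeric vector of dry weights (g).
#' @export
predict_dry_weight <- function(models, species, wet_g, count) {
  np_assert(all(wet_g >= 0), "pooled wet weights must be >= 0")
  np_assert(all(count >= 0), "counts must be >= 0")
  np_assert(all(wet_g[count == 0] == 0), "count 0 requires wet weight 0")
  idx <- match(species, models$species)
  if (anyNA(idx)) {
    np_stop("no allometric model for species: ",
            paste(unique(species[is.na(idx)]), collapse = ", "))
  }
  b1 <- models$slope[idx]
  b0 <- ifelse(models$intercept_dropped[idx], 0, models$intercept[idx])
  dw <- count * b0 + b1 * wet_g
  neg <- dw < 0
  if (any(neg)) {
    warn(paste0(sum(neg), " dry-weight prediction(s) below zero floored at 0"))
    dw[neg] <- 0
  }
  dw
}

#' Add predicted dry weights to a catch table
#'
#' @param catch Catch table with `species`, `count`, `wet_weight_g`.
#' @param models An `allometry_fit` table.
#' @return The catch table with a `dry_weight_g` column appended.
#' @export
add_dry_weight <- function(catch, models) {
  require_columns(catch, c("species", "count", "wet_weight_g"), "catch")
  mutate(catch, dry_weight_g = predict_dry_weight(models, species, wet_weight_g, count))
}

#' Mean tissue water content per species
#'
#' Mean and standard error, over individuals, of `1 - dry_g / wet_g`.
#'
#' @inheritParams fit_wet_dry
#' @return A tibble with `species`, `water_content_mean`, `water_content_se`
#'   (NA for a single record), `n`.
#' @export
water_content_summary <- function(wetdry) {
  require_columns(wetdry, c("species", "wet_g", "dry_g"), "wetdry")
  wetdry |>
    group_by(species) |>
    summarise(water_content_mean = mean(1 - dry_g / wet_g),
              water_content_se = se_mean(1 - dry_g / wet_g),
              n = n(), .groups = "drop")
}
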