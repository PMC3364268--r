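metrics_from <- function(values, ids = sprintf("S%03d", seq_along(values))) {
  tibble::tibble(sample_id = ids, density_ind_m2 = values,
                 biomass_gdw_m2 = values, energy_cal_m2 = values)
}

test_that("the subsidized proportion is a ratio of totals", {
  m <- metrics_from(c(10, 20, 30))
  fl <- toy_flags(m$sample_id, c(TRUE, TRUE, FALSE))
  out <- pulse_proportion(m, fl, "density")
  expect_equal(out$proportion, 30 / 60)
  expect_equal(out$n_subsidized, 2L)
  # all subsidized -> proportion 1 for every metric
  fl1 <- toy_flags(m$sample_id, rep(TRUE, 3))
  props <- pulse_proportions(m, fl1)
  expect_true(all(props$proportion == 1))
})

test_that("the unit metric reproduces subsidized sample shares exactly", {
  m <- metrics_from(runif(66, 1, 50))
  fl <- toy_flags(m$sample_id, c(rep(TRUE, 60), rep(FALSE, 6)))
  out <- pulse_proportion(m, fl, "unit")
  expect_equal(out$proportion, 60 / 66)
  expect_equal(round(100 * out$proportion), 91)
})

test_that("zero totals give proportion 0 with a warning; missing flags error", {
  m <- metrics_from(c(0, 0))
  fl <- toy_flags(m$sample_id, c(TRUE, FALSE))
  expect_warning(out <- pulse_proportion(m, fl, "energy"), "zero")
  expect_equal(out$proportion, 0)
  expect_error(pulse_proportion(metrics_from(1:3), fl[1:2, ], "density"),
               "missing")
})

test_that("cross-pulse averaging uses the two-pulse SE formula", {
  props <- tibble::tibble(pulse_id = c("feb", "mar"), metric = "density",
                          proportion = c(0.505, 0.847))
  out <- cross_pulse_mean(props)
  expect_equal(out$proportion_pct, 67.6)
  expect_equal(out$proportion_se_pct, 100 * abs(0.505 - 0.847) / 2)
  expect_equal(out$proportion_se_pct, 17.1)
  # equal proportions -> SE 0; a single pulse -> SE missing
  eq <- cross_pulse_mean(tibble::tibble(pulse_id = c("a", "b"), metric = "x",
                                        proportion = c(0.4, 0.4)))
  expect_equal(eq$proportion_se_pct, 0)
  single <- cross_pulse_mean(tibble::tibble(pulse_id = "a", metric = "x",
                                            proportion = 0.62))
  expect_true(is.na(single$proportion_se_pct))
})

test_that("inflow means pool both pulses' samples", {
  m <- metrics_from(c(30, 50))
  out <- inflow_means(m)
  expect_true(all(out$inflow_mean == 40))
  expect_true(all(out$inflow_se == 10))
  one <- inflow_means(metrics_from(rep(7, 5)))
  expect_true(all(one$inflow_mean == 7))
  expect_true(all(one$inflow_se == 0))
})

test_that("the subsidy estimate scales the mean by the subsidized percentage", {
  est <- subsidy_estimate(40.0, 7.2, 67.6, 17.1)
  expect_equal(round(est$Z, 1), 27.0)
  # quadrature error: direct evaluation of the stated rule
  expect_equal(est$Z_err, 27.04 * sqrt((7.2 / 40)^2 + (17.1 / 67.6)^2),
               tolerance = 1e-12)
  expect_equal(est$Z_err, 8.4, tolerance = 0.05)
  est2 <- subsidy_estimate(1.3, 0.2, 61.1, 12.1)
  expect_equal(round(est2$Z, 1), 0.8)
})

test_that("error rules and degenerate inputs behave as documented", {
  # Y_err = 0 collapses quadrature to the single relative error
  e <- subsidy_estimate(10, 2, 50, 0)
  expect_equal(e$Z_err, e$Z * 2 / 10)
  # Y = 0 -> zero subsidy with zero error
  e0 <- subsidy_estimate(10, 2, 0, 5)
  expect_equal(e0$Z, 0)
  expect_equal(e0$Z_err, 0)
  ep <- subsidy_estimate(40, 7.2, 67.6, 17.1, error_rule = "product")
  expect_equal(ep$Z_err, ep$Z * (7.2 / 40) * (17.1 / 67.6))
  em <- subsidy_estimate(40, 7.2, 67.6, 17.1, error_rule = "mean_only")
  expect_equal(em$Z_err, ep$Z * 7.2 / 40)
  expect_equal(em$Z_err, 4.9, tolerance = 0.05) # near the 4.8 scale of X_err * Y
  expect_error(subsidy_estimate(-1, 1, 50, 5), "positive")
})

test_that("the subsidy is linear in both the mean and the percentage", {
  base <- subsidy_estimate(20, 1, 40, 2)
  expect_equal(subsidy_estimate(60, 1, 40, 2)$Z, 3 * base$Z)
  expect_equal(subsidy_estimate(20, 1, 80, 2)$Z, 2 * base$Z)
  expect_true(base$Z <= 20) # Z <= X whenever Y <= 100
})

test_that("subsidy_table assembles one row per metric at full precision", {
  m <- tibble::tibble(sample_id = sprintf("S%03d", 1:6),
                      density_ind_m2 = c(10, 20, 30, 5, 15, 25),
                      biomass_gdw_m2 = c(1, 2, 3, 0.5, 1.5, 2.5),
                      energy_cal_m2 = c(100, 200, 300, 50, 150, 250))
  fl <- dplyr::bind_rows(
    toy_flags(m$sample_id[1:3], c(TRUE, TRUE, FALSE), "feb"),
    toy_flags(m$sample_id[4:6], c(TRUE, FALSE, FALSE), "mar"))
  tab <- subsidy_table(m, fl)
  expect_s3_class(tab, "nekton_subsidy")
  expect_equal(tab$metric, c("density", "biomass", "energy"))
  p_feb <- 30 / 60; p_mar <- 5 / 45
  expect_equal(tab$proportion_pct[1], 100 * mean(c(p_feb, p_mar)))
  expect_equal(tab$inflow_mean[1], mean(m$density_ind_m2))
  expect_equal(tab$subsidy[1], tab$inflow_mean[1] * tab$proportion_pct[1] / 100)
  # double-rounding guard: rounding the full-precision subsidy once equals
  # rounding the product of the unrounded mean and proportion
  expect_equal(round(tab$subsidy, 1),
               round(tab$inflow_mean * tab$proportion_pct / 100, 1))
})
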