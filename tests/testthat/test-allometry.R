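test_that("records on an exact through-origin line recover it with r2 = 1", {
  wd <- tibble::tibble(species = "sp", wet_g = c(0.5, 1, 2, 3.5, 5),
                       dry_g = 0.2 * c(0.5, 1, 2, 3.5, 5))
  # summary.lm warns about the zero-residual fit; that is the scenario under test
  fit <- suppressWarnings(fit_wet_dry(wd))
  expect_equal(fit$slope, 0.2, tolerance = 1e-12)
  expect_true(fit$intercept_dropped)
  expect_true(is.na(fit$intercept))
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("the fit reproduces the closed-form normal-equation solution", {
  # 5-point hand data set, checked against solve(t(X) X) b = t(X) y
  wd <- tibble::tibble(species = "sp", wet_g = 1:5,
                       dry_g = c(0.21, 0.38, 0.62, 0.79, 1.02))
  X <- cbind(1, wd$wet_g)
  beta <- unname(solve(t(X) %*% X, t(X) %*% wd$dry_g)[, 1])
  fit <- fit_wet_dry(wd, alpha = 0.5) # generous alpha so the intercept survives gating
  if (fit$intercept_dropped) {
    b1 <- sum(wd$wet_g * wd$dry_g) / sum(wd$wet_g^2)
    expect_equal(fit$slope, b1, tolerance = 1e-12)
  } else {
    expect_equal(fit$intercept, beta[1], tolerance = 1e-10)
    expect_equal(fit$slope, beta[2], tolerance = 1e-10)
  }

  # property: random small data sets, both model forms, <= 1e-10 relative error
  set.seed(99)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    ww <- runif(n, 0.05, 3)
    dw <- pmin(pmax(0.005 + 0.2 * ww + rnorm(n, 0, 0.02), 0.01 * ww), 0.95 * ww)
    wdi <- tibble::tibble(species = "z", wet_g = ww, dry_g = dw)
    f <- fit_wet_dry(wdi)
    if (f$intercept_dropped) {
      expect_equal(f$slope, sum(ww * dw) / sum(ww^2), tolerance = 1e-10)
    } else {
      Xi <- cbind(1, ww)
      b <- unname(solve(t(Xi) %*% Xi, t(Xi) %*% dw)[, 1])
      expect_equal(f$intercept, b[1], tolerance = 1e-10)
      expect_equal(f$slope, b[2], tolerance = 1e-10)
    }
  }
})

test_that("degenerate inputs are rejected with informative errors", {
  expect_error(fit_wet_dry(tibble::tibble(species = "a", wet_g = c(1, 2),
                                          dry_g = c(0.2, 0.4))), "at least 3")
  expect_error(fit_wet_dry(tibble::tibble(species = "a", wet_g = rep(2, 5),
                                          dry_g = rep(0.4, 5))), "variance")
  expect_error(fit_wet_dry(tibble::tibble(species = "a", wet_g = 1:3,
                                          dry_g = c(0.2, 0.4, 3.5))), "dry_g < wet_g")
  expect_error(fit_wet_dry(tibble::tibble(species = "a", wet_g = 1:3,
                                          dry_g = 0.2 * (1:3)), alpha = 0.7), "alpha")
})

test_that("water content summary matches hand computation", {
  wd <- tibble::tibble(species = "a", wet_g = c(1, 1), dry_g = c(0.22, 0.16))
  out <- water_content_summary(wd)
  expect_equal(out$water_content_mean, 0.81)
  expect_equal(out$water_content_se, 0.03)
  # constant water content -> SE 0; single record -> SE missing
  wd2 <- tibble::tibble(species = "b", wet_g = c(1, 2, 4), dry_g = 0.19 * c(1, 2, 4))
  out2 <- water_content_summary(wd2)
  expect_equal(out2$water_content_mean, 0.81)
  expect_equal(out2$water_content_se, 0)
  out3 <- water_content_summary(tibble::tibble(species = "c", wet_g = 1, dry_g = 0.2))
  expect_true(is.na(out3$water_content_se))
})

test_that("dry-weight prediction applies the per-individual intercept", {
  models <- toy_models(species = c("orig", "int"), slope = c(0.21, 0.206633),
                       intercept = c(NA, -0.002934))
  # printed-equation check: one individual at 1 g WW
  expect_equal(predict_dry_weight(models, "int", 1.0, 1), 0.203699)
  # intercept scales with the individual count
  expect_equal(predict_dry_weight(models, "int", 2.0, 5),
               5 * -0.002934 + 0.206633 * 2)
  # through-origin prediction ignores the count
  expect_equal(predict_dry_weight(models, "orig", 1.5, 1),
               predict_dry_weight(models, "orig", 1.5, 50))
  expect_equal(predict_dry_weight(models, "orig", 0, 0), 0)
  expect_error(predict_dry_weight(models, "unknown", 1, 1), "unknown")
  expect_error(predict_dry_weight(models, "orig", 1, 0), "count 0")
})

test_that("negative predictions are floored at zero with a warning", {
  models <- toy_models(species = "int", slope = 0.2, intercept = -0.05)
  expect_warning(dw <- predict_dry_weight(models, "int", 0.1, 2), "floored")
  expect_equal(dw, 0)
})

test_that("prediction is additive and homogeneous for the intercept model", {
  models <- toy_models(species = c("A", "B"), slope = c(0.2, 0.24),
                       intercept = c(-0.01, -0.02))
  # additive over species-disjoint catches
  a <- predict_dry_weight(models, "A", 1.2, 3)
  b <- predict_dry_weight(models, "B", 0.8, 2)
  both <- predict_dry_weight(models, c("A", "B"), c(1.2, 0.8), c(3, 2))
  expect_equal(sum(both), a + b)
  # degree-1 homogeneous in (count, pooled weight)
  expect_equal(predict_dry_weight(models, "A", 3 * 1.2, 3 * 3), 3 * a)
})

test_that("tidy and glance methods summarise the fit table", {
  wd <- simulate_wet_dry(allometry_truth(), seed = 5)
  fit <- fit_wet_dry(wd)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$species, dominant_species())
  gl <- glance(fit)
  expect_equal(gl$n_species, 6)
  expect_equal(gl$n_individuals, sum(allometry_truth()$n_individuals))
})
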