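test_that("threshold-curve algebra inverts the logistic coefficients", {
  cu <- threshold_curve(fake_fit(c(-6, -90, 0.1)))
  expect_equal(cu$dGmin, 60)
  expect_equal(cu$SRmin, 900)
  expect_equal(threshold_at(cu, 0.1), 150)
  expect_equal(threshold_at(cu, 0), 60)
  expect_error(threshold_at(cu, -0.1), "non-negative")

  # covariate main effect shifts the intercept only
  f <- fake_fit(c(-6, -90, 0.1, 0.2, 0), covariates = "age",
                centers = c(age = 40))
  cu <- threshold_curve(f, covariates = list(age = 50))  # phi' = 10
  expect_equal(cu$dGmin, 60 - (0.2 / 0.1) * 10)
  expect_equal(cu$SRmin, 900)

  expect_error(threshold_curve(fake_fit(c(-6, -90, 0))), "degenerate")
  expect_warning(threshold_curve(fake_fit(c(6, 90, -0.1))), "negative")
})

test_that("the curve lies on the fitted 50% probability contour", {
  coh <- read_site_fixture("berkeley")
  for (covs in list(character(), c("age", "sex"))) {
    fit <- fit_pns_model(coh, "x", covariates = covs)
    ctx <- if (length(covs)) list(age = 47, sex = 1) else list()
    cu <- threshold_curve(fit, covariates = ctx)
    for (tau in c(0.05, 0.1, 0.37, 0.5, 1.2)) {
      expect_equal(
        predict_probability(fit, tau, threshold_at(cu, tau), ctx), 0.5,
        tolerance = 1e-9)
    }
  }
})

test_that("shifting a covariate and its center together changes nothing", {
  coh <- read_site_fixture("berkeley")
  obs <- compute_cell_weights(expand_measurements(coh))
  obs <- obs[obs$axis == "x", ]
  fit1 <- fit_weighted_logistic(
    center_covariates(obs, covariate_spec(obs, "age")),
    obs$response, obs$weight)
  delta <- 7
  obs2 <- obs
  obs2$age_years <- obs2$age_years + delta
  spec2 <- covariate_spec(obs2, "age")
  expect_equal(spec2$centers[["age"]],
               covariate_spec(obs, "age")$centers[["age"]] + delta)
  fit2 <- fit_weighted_logistic(center_covariates(obs2, spec2),
                                obs2$response, obs2$weight)
  expect_equal(fit1$coefficients, fit2$coefficients, tolerance = 1e-6)
})

test_that("z-offset sensitivity follows the coefficient ratio", {
  f <- fake_fit(c(-6, -90, 0.1, -2, 0), covariates = "z_offset")
  expect_equal(z_sensitivity(f), 20)
  expect_equal(z_sensitivity(f, tau_ref = 0.5), 20)  # no interaction
  f2 <- fake_fit(c(-6, -90, 0.1, -2, -1), covariates = "z_offset")
  expect_equal(z_sensitivity(f2, tau_ref = 0.3), (2 + 0.3) / 0.1)
  expect_error(z_sensitivity(fake_fit(c(-6, -90, 0.1))), "z_offset")
})

test_that("per-subject lines match closed-form least squares", {
  coh <- read_site_fixture("berkeley")
  m <- coh$measurements
  s1 <- m[m$subject_id == "1" & m$axis == "x", ]
  f <- per_subject_linear_fit(s1, coh$envelope)
  # closed-form OLS oracle on the printed points
  tau <- c(0.1, 0.22, 0.3, 0.5)
  amp <- c(62, 82, 96, 116)
  slope <- sum((tau - mean(tau)) * (amp - mean(amp))) /
    sum((tau - mean(tau))^2)
  expect_true(f$ok)
  expect_equal(f$slope, slope)
  expect_equal(f$intercept, mean(amp) - slope * mean(tau))
  # residuals orthogonal to the regressor
  res <- amp - (f$intercept + f$slope * tau)
  expect_equal(sum(res * tau), 0, tolerance = 1e-9)
})

test_that("censoring rules and degenerate inputs are handled", {
  coh <- make_test_cohort()
  s2 <- coh$measurements[coh$measurements$subject_id == "s2", ]
  # cap_plus_one: the 0.1-ms censored point becomes 90 + 1 = 91
  f <- per_subject_linear_fit(s2, coh$envelope, censor_rule = "cap_plus_one")
  expect_true(f$ok)
  expect_equal(f$n_censored, 1L)
  expect_equal(f$slope, (120 - 91) / (0.3 - 0.1))
  # omit: only one usable point left -> flagged, no fit
  f <- per_subject_linear_fit(s2, coh$envelope, censor_rule = "omit")
  expect_false(f$ok)
  # two points give the exact interpolating line
  s1 <- coh$measurements[coh$measurements$subject_id == "s1", ]
  f <- per_subject_linear_fit(s1, coh$envelope)
  expect_equal(f$intercept + 0.1 * f$slope, 62)
  expect_equal(f$intercept + 0.3 * f$slope, 96)
  # all censored with omit -> no fit
  allc <- s2
  allc$status <- "no_pns"
  allc$amplitude_mTm <- NA
  expect_false(per_subject_linear_fit(allc, coh$envelope, "omit")$ok)
})

test_that("population fits on every real axis give rising thresholds", {
  for (site in c("berkeley", "erlangen")) {
    coh <- read_site_fixture(site)
    for (ax in c("x", "y", "z")) {
      fit <- fit_pns_model(coh, ax)
      expect_true(fit$converged)
      cu <- threshold_curve(fit)
      expect_gt(cu$SRmin, 0)
      expect_gt(cu$dGmin, 0)
      tt <- threshold_at(cu, c(0.1, 0.3, 0.5))
      expect_true(all(diff(tt) > 0))
    }
  }
})
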