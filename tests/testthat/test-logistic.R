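test_that("design rows carry centered covariates and their interactions", {
  obs <- structure(data.frame(
    subject_id = c("a", "b"), axis = "x", z_offset_cm = c(0, 2),
    rise_time_ms = c(0.1, 0.5), amplitude_mTm = c(60, 120),
    response = c(0L, 1L), weight = 1, age_years = c(60, 44.4),
    sex_code = c(1L, 0L)), class = c("pns_observations", "data.frame"))
  spec <- covariate_spec(obs, c("age", "z_offset"),
                         centers = c(age = 52.2))
  X <- center_covariates(obs, spec)
  expect_equal(colnames(X), c("(Intercept)", "tau", "dG", "age", "age:tau",
                              "z_offset", "z_offset:tau"))
  expect_equal(unname(X[1, "age"]), 7.8)
  expect_equal(unname(X[1, "age:tau"]), 0.78)
  # z_offset center is pinned at 0 regardless of the data
  expect_equal(spec$centers[["z_offset"]], 0)
  expect_equal(unname(X[2, "z_offset"]), 2)
  # no covariates: the three-column base model
  X0 <- center_covariates(obs, covariate_spec(obs))
  expect_equal(ncol(X0), 3)
})

test_that("a symmetric separable pair puts the midpoint at 50%", {
  X <- cbind("(Intercept)" = 1, dG = c(40, 60))
  f <- fit_weighted_logistic(X, c(0, 1), ridge = 1e-6)
  b <- f$coefficients
  expect_equal(unname(plogis(b[1] + b[2] * 50)), 0.5, tolerance = 1e-6)
})

test_that("IRLS matches direct likelihood maximization on small data", {
  for (seed in 1:6) {
    d <- random_logit_data(seed, n = sample(6:12, 1))
    f <- fit_weighted_logistic(d$X, d$y, d$w, ridge = 1e-6)
    expect_true(f$converged)
    oracle <- optim_logit(d$X, d$y, d$w, ridge = 1e-6,
                          start = f$coefficients * 1.05)
    expect_equal(unname(f$coefficients), unname(oracle),
                 tolerance = 1e-4)
  }
})

test_that("duplicating an observation equals doubling its weight", {
  d <- random_logit_data(16, n = 10)
  f_dup <- fit_weighted_logistic(rbind(d$X, d$X[3, ]), c(d$y, d$y[3]),
                                 c(d$w, d$w[3]))
  w2 <- d$w
  w2[3] <- 2 * w2[3]
  f_wt <- fit_weighted_logistic(d$X, d$y, w2)
  expect_equal(f_dup$coefficients, f_wt$coefficients, tolerance = 1e-9)
  expect_equal(f_dup$loglik, f_wt$loglik, tolerance = 1e-9)
})

test_that("fits are invariant to the rise-time unit after conversion", {
  d <- random_logit_data(5, n = 12)
  f_ms <- fit_weighted_logistic(d$X, d$y, d$w)
  X_us <- d$X
  X_us[, "tau"] <- X_us[, "tau"] * 1000
  f_us <- fit_weighted_logistic(X_us, d$y, d$w)
  p_ms <- plogis(drop(d$X %*% f_ms$coefficients))
  p_us <- plogis(drop(X_us %*% f_us$coefficients))
  expect_equal(p_ms, p_us, tolerance = 1e-8)
})

test_that("with equal weights the fit reduces to ordinary logistic glm", {
  d <- random_logit_data(9, n = 40)
  f <- fit_weighted_logistic(d$X, d$y, rep(1, length(d$y)))
  g <- stats::glm(d$y ~ d$X[, "tau"] + d$X[, "dG"],
                  family = stats::binomial())
  expect_equal(unname(f$coefficients), unname(coef(g)), tolerance = 1e-6)
  expect_equal(unname(f$se), unname(sqrt(diag(stats::vcov(g)))),
               tolerance = 1e-4)
})

test_that("known coefficients are recovered within 3 SE at n = 2000", {
  set.seed(123)
  n <- 2000
  beta <- c(-6, -9, 0.08)
  tau <- sample(c(0.1, 0.22, 0.3, 0.5), n, replace = TRUE)
  dG <- runif(n, 20, 200)
  X <- cbind("(Intercept)" = 1, tau = tau, dG = dG)
  y <- rbinom(n, 1, plogis(drop(X %*% beta)))
  f <- fit_weighted_logistic(X, y)
  expect_true(f$converged)
  expect_true(all(abs(f$coefficients - beta) <= 3 * f$se))
})

test_that("complete separation is flagged; ridge restores convergence", {
  X <- cbind("(Intercept)" = 1, dG = c(10, 20, 30, 80, 90, 100))
  y <- c(0, 0, 0, 1, 1, 1)
  f <- suppressWarnings(fit_weighted_logistic(X, y))
  expect_false(f$converged)
  f_r <- fit_weighted_logistic(X, y, ridge = 1e-6)
  expect_true(f_r$converged)
  expect_error(fit_weighted_logistic(X, rep(1, 6)), "each class")
})

test_that("predicted probabilities follow the logistic model", {
  f <- fake_fit(c(-6, -90, 0.1))
  # linear predictor zero at dG = 60 + 900 * tau
  expect_equal(predict_probability(f, 0.2, 60 + 0.2 * 900), 0.5)
  expect_equal(predict_probability(f, 0.3, 60 + 0.3 * 900), 0.5)
  # strictly increasing in amplitude when the amplitude coefficient > 0
  p <- predict_probability(f, 0.3, seq(50, 400, by = 25))
  expect_true(all(diff(p) > 0))
  # covariate values are required when the fit has covariates
  f2 <- fake_fit(c(-6, -90, 0.1, 0.2, 0), covariates = "age",
                 centers = c(age = 50))
  expect_error(predict_probability(f2, 0.3, 100), "age")
  expect_equal(predict_probability(f2, 0.2, 240, list(age = 50)), 0.5)
})
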