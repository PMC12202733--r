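# Shared fixtures and oracles, built in code.

# A small hand-constructed cohort: three subjects, x axis, two rise times.
make_test_cohort <- function() {
  subjects <- data.frame(
    subject_id = c("s1", "s2", "s3"),
    site = "berkeley",
    sex = c("M", "F", "M"),
    age_years = c(40, 60, 30),
    height_cm = c(180, NA, 170),
    weight_kg = c(80, 60, NA))
  measurements <- data.frame(
    subject_id = rep(c("s1", "s2", "s3"), each = 2),
    axis = "x",
    z_offset_cm = 0,
    rise_time_ms = rep(c(0.1, 0.3), 3),
    status = c("threshold", "threshold",
               "no_pns", "threshold",
               "threshold", "not_tested"),
    amplitude_mTm = c(62, 96, NA, 120, 2, NA),
    location = "")
  structure(list(subjects = subjects, measurements = measurements,
                 envelope = hardware_envelope()),
            class = "pns_cohort")
}

# A pns_model object with prescribed coefficients, for threshold algebra.
fake_fit <- function(beta, covariates = character(), centers = NULL,
                     axis = "x") {
  nm <- c("(Intercept)", "tau", "dG")
  for (cv in covariates) nm <- c(nm, cv, paste0(cv, ":tau"))
  stopifnot(length(beta) == length(nm))
  ctr <- setNames(rep(0, length(covariates)), covariates)
  if (!is.null(centers)) ctr[names(centers)] <- centers
  if ("z_offset" %in% covariates) ctr[["z_offset"]] <- 0
  spec <- structure(list(names = covariates, centers = ctr),
                    class = "pns_covariate_spec")
  structure(list(coefficients = setNames(beta, nm), converged = TRUE,
                 spec = spec, axis = axis),
            class = c("pns_model", "pns_logit"))
}

# Independent direct maximization of the weighted (ridge-penalized)
# Bernoulli log-likelihood, used as the oracle for the IRLS fit.
optim_logit <- function(X, y, w, ridge = 0, start = NULL) {
  X <- as.matrix(X)
  pen <- rep(ridge, ncol(X))
  if (!is.null(colnames(X))) pen[colnames(X) == "(Intercept)"] <- 0
  nll <- function(b) {
    eta <- drop(X %*% b)
    log1pe <- ifelse(eta > 30, eta, log1p(exp(eta)))
    -(sum(w * (y * eta - log1pe)) - sum(pen * b^2) / 2)
  }
  if (is.null(start)) start <- numeric(ncol(X))
  o <- stats::optim(start, nll, method = "Nelder-Mead",
                    control = list(maxit = 1e5, reltol = 1e-15))
  # polish with a second pass from the first optimum
  o <- stats::optim(o$par, nll, method = "Nelder-Mead",
                    control = list(maxit = 1e5, reltol = 1e-15))
  o$par
}

# Random small weighted logistic datasets with both response classes.
random_logit_data <- function(seed, n = 10) {
  set.seed(seed)
  repeat {
    tau <- sample(c(0.1, 0.22, 0.3, 0.5), n, replace = TRUE)
    dG <- runif(n, 30, 190)
    p <- plogis(-4 - 8 * tau + 0.05 * dG)
    y <- rbinom(n, 1, p)
    if (any(y == 0) && any(y == 1)) break
  }
  list(X = cbind("(Intercept)" = 1, tau = tau, dG = dG), y = y,
       w = round(runif(n, 0.1, 1), 3))
}
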