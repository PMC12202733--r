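#' Covariate specification with centering
#'
#' Covariates enter the logistic model as centered values `phi' = phi -
#' center` together with their rise-time interactions `phi' * tau`. Age is
#' centered at the population mean over the fitted subjects, sex (coded
#' F = 0, M = 1) at its mean, and the bore Z-offset is centered at 0 so that
#' the reference curve is the isocenter curve.
#'
#' @param observations A `pns_observations` data frame (used to compute the
#'   default centers over the unique subjects it contains).
#' @param covariates Subset of `c("age", "sex", "z_offset")`, in model
#'   order.
#' @param centers Optional named numeric vector overriding the computed
#'   centers; the `z_offset` center is always forced to 0.
#' @return An object of class `pns_covariate_spec` with `names` and
#'   `centers`.
#' @export
covariate_spec <- function(observations, covariates = character(),
                           centers = NULL) {
  allowed <- c("age", "sex", "z_offset")
  if (!all(covariates %in% allowed)) {
    stop("covariates must be among: ", paste(allowed, collapse = ", "))
  }
  col_of <- c(age = "age_years", sex = "sex_code", z_offset = "z_offset_cm")
  first <- !duplicated(observations$subject_id)
  ctr <- vapply(covariates, function(cv) {
    v <- observations[[col_of[[cv]]]][first]
    if (anyNA(v)) stop("missing ", cv, " value for subject ",
                       observations$subject_id[first][which(is.na(v))[1]])
    mean(v)
  }, numeric(1))
  if (!is.null(centers)) ctr[names(centers)] <- centers
  if ("z_offset" %in% covariates) ctr[["z_offset"]] <- 0
  if (length(ctr) && any(!is.finite(ctr))) stop("centers must be finite")
  structure(list(names = covariates, centers = ctr, columns = col_of),
            class = "pns_covariate_spec")
}

#' Build the centered design matrix
#'
#' Row layout: `[1, tau, dG, phi'_1, phi'_1 * tau, ..., phi'_N,
#' phi'_N * tau]`, giving `3 + 2 N` columns.
#'
#' @param observations A `pns_observations` data frame.
#' @param spec A [covariate_spec()].
#' @return Numeric design matrix with named columns.
#' @export
center_covariates <- function(observations, spec) {
  stopifnot(inherits(spec, "pns_covariate_spec"))
  tau <- observations$rise_time_ms
  X <- cbind("(Intercept)" = rep(1, nrow(observations)),
             tau = tau, dG = observations$amplitude_mTm)
  for (cv in spec$names) {
    v <- observations[[spec$columns[[cv]]]]
    if (anyNA(v)) {
      stop("missing ", cv, " value for subject ",
           observations$subject_id[which(is.na(v))[1]])
    }
    phi <- v - spec$centers[[cv]]
    add <- cbind(phi, phi * tau)
    colnames(add) <- c(cv, paste0(cv, ":tau"))
    X <- cbind(X, add)
  }
  X
}

#' Weighted logistic regression by iteratively reweighted least squares
#'
#' Maximizes the weighted Bernoulli log-likelihood `sum(w * (S * log(p) +
#' (1 - S) * log(1 - p)))` with `p = plogis(X beta)` by Newton/IRLS with
#' step-halving. Standard errors come from the inverse weighted Fisher
#' information at the optimum; Wald z-tests are two-sided.
#'
#' @param X Design matrix (see [center_covariates()]).
#' @param y Binary responses (0/1).
#' @param w Non-negative observation weights; rows with zero weight are
#'   dropped.
#' @param tol Convergence tolerance on the maximum absolute score
#'   component.
#' @param max_iter Maximum Newton iterations.
#' @param ridge Optional L2 penalty `ridge / 2 * sum(beta_j^2)` over all
#'   coefficients except the intercept, stabilizing separated data; 0
#'   (default) is the plain maximum-likelihood fit.
#' @return An object of class `pns_logit` with elements `coefficients`,
#'   `se`, `z`, `p_value`, `vcov`, `loglik`, `n`, `converged`,
#'   `iterations`, `max_score`, `ridge`.
#' @export
fit_weighted_logistic <- function(X, y, w = rep(1, length(y)), tol = 1e-8,
                                  max_iter = 100, ridge = 0) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), length(w) == length(y), all(w >= 0),
            all(y %in% c(0, 1)), ridge >= 0)
  keep <- w > 0
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  w <- w[keep]
  if (!any(y == 0) || !any(y == 1)) {
    stop("need at least one response of each class among positive-weight rows")
  }
  p_dim <- ncol(X)
  # the intercept is never penalized
  pen <- rep(ridge, p_dim)
  if (!is.null(colnames(X))) pen[colnames(X) == "(Intercept)"] <- 0

  pen_ll <- function(beta) {
    eta <- drop(X %*% beta)
    # stable log(1 + exp(eta))
    log1pe <- ifelse(eta > 30, eta, log1p(exp(eta)))
    sum(w * (y * eta - log1pe)) - sum(pen * beta^2) / 2
  }

  beta <- numeric(p_dim)
  ll <- pen_ll(beta)
  converged <- FALSE
  max_score <- Inf
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    score <- drop(crossprod(X, w * (y - p))) - pen * beta
    max_score <- max(abs(score))
    if (max_score < tol) {
      converged <- TRUE
      break
    }
    wt <- w * p * (1 - p)
    info <- crossprod(X, X * wt) + diag(pen, p_dim)
    delta <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(delta)) break
    step <- 1
    repeat {
      cand <- beta + step * delta
      ll_new <- pen_ll(cand)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      step <- step / 2
      if (step < 1e-10) break
    }
    if (step < 1e-10) break
    beta <- beta + step * delta
    ll <- ll_new
  }
  if (converged) {
    # one more score evaluation at the accepted beta
    p <- plogis(drop(X %*% beta))
    max_score <- max(abs(drop(crossprod(X, w * (y - p))) - pen * beta))
    converged <- max_score < tol
  }
  p <- plogis(drop(X %*% beta))
  if (ridge == 0 && all(abs(y - p) < 1e-4)) {
    # perfect classification: the unpenalized likelihood has no maximum
    converged <- FALSE
    warning("complete separation: every observation is perfectly ",
            "classified, the maximum-likelihood estimate diverges; ",
            "consider a small ridge > 0")
  }
  info <- crossprod(X, X * (w * p * (1 - p)))
  vc <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, p_dim, p_dim)
  })
  se <- sqrt(pmax(diag(vc), 0))
  zv <- beta / se
  names(beta) <- colnames(X)
  structure(list(coefficients = setNames(beta, colnames(X)),
                 se = setNames(se, colnames(X)),
                 z = setNames(zv, colnames(X)),
                 p_value = setNames(2 * pnorm(-abs(zv)), colnames(X)),
                 vcov = vc,
                 loglik = pen_ll(beta) + sum(pen * beta^2) / 2,
                 n = length(y), converged = converged, iterations = iter,
                 max_score = max_score, ridge = ridge),
            class = "pns_logit")
}

#' @export
print.pns_logit <- function(x, ...) {
  cat("Weighted logistic fit (", x$n, " observations, ",
      if (x$converged) "converged" else "NOT converged",
      " in ", x$iterations, " iterations)\n", sep = "")
  print(data.frame(estimate = x$coefficients, se = x$se, z = x$z,
                   p = signif(x$p_value, 3)))
  invisible(x)
}

#' Fit the population PNS model for one axis
#'
#' End-to-end wrapper: expands the cohort's measurements for one gradient
#' axis into weighted binary observations, computes per-cell stimulated
#' fractions as fitting weights, centers the requested covariates and runs
#' the IRLS fit.
#'
#' @param cohort A `pns_cohort`.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param covariates Subset of `c("age", "sex", "z_offset")`.
#' @param protocol,envelope,mode Passed to [expand_measurements()].
#' @param weighting `"cell_fraction"` or `"uniform"`.
#' @param weight_by Cell definition for [compute_cell_weights()].
#' @param ... Further arguments to [fit_weighted_logistic()] (`tol`,
#'   `max_iter`, `ridge`).
#' @return A `pns_model` object: the `pns_logit` fit plus `spec`, `axis`
#'   and the observations used.
#' @examples
#' coh <- read_site_fixture("berkeley")
#' fit <- fit_pns_model(coh, axis = "x")
#' threshold_curve(fit)
#' @export
fit_pns_model <- function(cohort, axis, covariates = character(),
                          protocol = protocol_config(), envelope = NULL,
                          mode = c("grid", "bracket"),
                          weighting = c("cell_fraction", "uniform"),
                          weight_by = c("axis", "rise_time_ms"), ...) {
  stopifnot(inherits(cohort, "pns_cohort"), axis %in% .axes)
  weighting <- match.arg(weighting)
  obs <- expand_measurements(cohort, protocol = protocol,
                             envelope = envelope, mode = match.arg(mode))
  obs <- obs[obs$axis == axis, , drop = FALSE]
  if (nrow(obs) == 0) stop("no observations on axis ", axis)
  obs <- compute_cell_weights(obs, by = weight_by, scheme = weighting)
  spec <- covariate_spec(obs, covariates)
  X <- center_covariates(obs, spec)
  fit <- fit_weighted_logistic(X, obs$response, obs$weight, ...)
  fit$spec <- spec
  fit$axis <- axis
  fit$observations <- obs
  class(fit) <- c("pns_model", class(fit))
  fit
}

#' @keywords internal
.linear_predictor <- function(fit, tau, dG, covariates = list()) {
  beta <- fit$coefficients
  spec <- fit$spec
  if (is.null(spec)) spec <- structure(list(names = character(),
                                            centers = numeric()),
                                       class = "pns_covariate_spec")
  eta <- beta[["(Intercept)"]] + beta[["tau"]] * tau + beta[["dG"]] * dG
  for (cv in spec$names) {
    if (is.null(covariates[[cv]])) {
      stop("covariate value for '", cv, "' is required")
    }
    phi <- covariates[[cv]] - spec$centers[[cv]]
    eta <- eta + beta[[cv]] * phi + beta[[paste0(cv, ":tau")]] * phi * tau
  }
  eta
}

#' Predicted stimulation probability
#'
#' @param fit A converged `pns_logit`/`pns_model`.
#' @param tau Rise time, ms.
#' @param dG Zero-to-peak amplitude, mT/m.
#' @param covariates Named list of covariate values (`age`, `sex` as 0/1,
#'   `z_offset` in cm) for every covariate in the fit.
#' @return Probability in `[0, 1]`, vectorized over `tau`/`dG`.
#' @export
predict_probability <- function(fit, tau, dG, covariates = list()) {
  stopifnot(inherits(fit, "pns_logit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  plogis(.linear_predictor(fit, tau, dG, covariates))
}
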