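#' Population threshold curve from a logistic fit
#'
#' The 50% stimulation contour of the fitted model is the line
#' `dG(tau) = dGmin + tau * SRmin` with
#' `dGmin = -(beta_0 + sum(beta_main * phi')) / beta_dG` and
#' `SRmin = -(beta_tau + sum(beta_int * phi')) / beta_dG`, where `phi'` are
#' the centered covariate values at which the curve is evaluated. `dGmin`
#' plays the role of a rheobase-like amplitude floor and `SRmin` of a
#' minimum usable slew rate.
#'
#' @param fit A converged `pns_model` (or `pns_logit` with a covariate
#'   spec attached).
#' @param covariates Named list of covariate values for every covariate in
#'   the fit (e.g. `list(age = 50, sex = 1, z_offset = 2)`).
#' @return An object of class `pns_threshold_curve` with `dGmin` (mT/m),
#'   `SRmin` (mT/m/ms), the covariate `context` and the `axis`.
#' @export
threshold_curve <- function(fit, covariates = list()) {
  stopifnot(inherits(fit, "pns_logit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  beta <- fit$coefficients
  b2 <- beta[["dG"]]
  if (b2 == 0) stop("degenerate model: amplitude coefficient is zero")
  if (b2 < 0) {
    warning("amplitude coefficient is negative; stimulation probability ",
            "decreasing in amplitude is nonphysical")
  }
  spec <- fit$spec
  nm <- if (is.null(spec)) character() else spec$names
  num_dg <- beta[["(Intercept)"]]
  num_sr <- beta[["tau"]]
  for (cv in nm) {
    if (is.null(covariates[[cv]])) {
      stop("covariate value for '", cv, "' is required")
    }
    phi <- covariates[[cv]] - spec$centers[[cv]]
    num_dg <- num_dg + beta[[cv]] * phi
    num_sr <- num_sr + beta[[paste0(cv, ":tau")]] * phi
  }
  structure(list(dGmin = -num_dg / b2, SRmin = -num_sr / b2,
                 context = covariates, axis = fit$axis, fit = fit),
            class = "pns_threshold_curve")
}

#' @export
print.pns_threshold_curve <- function(x, ...) {
  cat("PNS threshold curve", if (!is.null(x$axis)) paste0(" (", x$axis,
      "-axis)"), ": dG(tau) = ", round(x$dGmin, 2), " + tau * ",
      round(x$SRmin, 2), "  [mT/m, tau in ms]\n", sep = "")
  invisible(x)
}

#' Evaluate a threshold curve at a rise time
#'
#' @param curve A [threshold_curve()].
#' @param tau Rise time(s), ms; non-negative (`tau = 0` returns the
#'   `dGmin` intercept).
#' @return Threshold amplitude(s) `dGmin + tau * SRmin`, mT/m.
#' @export
threshold_at <- function(curve, tau) {
  stopifnot(inherits(curve, "pns_threshold_curve"))
  if (any(tau < 0)) stop("rise time must be non-negative")
  curve$dGmin + tau * curve$SRmin
}

#' Z-offset sensitivity of the threshold
#'
#' Derivative of the threshold amplitude with respect to the bore Z-offset
#' (cm toward the feet) at a reference rise time:
#' `-(beta_z + beta_ztau * tau_ref) / beta_dG`. Positive values mean the
#' threshold rises as the subject moves toward the foot end.
#'
#' @param fit A converged `pns_model` fitted with the `z_offset` covariate.
#' @param tau_ref Reference rise time, ms (default 0.3, the rise time used
#'   for positioning comparisons).
#' @return Sensitivity in mT/m per cm.
#' @export
z_sensitivity <- function(fit, tau_ref = 0.3) {
  stopifnot(inherits(fit, "pns_logit"))
  if (is.null(fit$spec) || !"z_offset" %in% fit$spec$names) {
    stop("fit does not include the z_offset covariate")
  }
  beta <- fit$coefficients
  -(beta[["z_offset"]] + beta[["z_offset:tau"]] * tau_ref) / beta[["dG"]]
}

#' Per-subject linear threshold fit
#'
#' Ordinary least squares of threshold amplitude on rise time for one
#' subject and axis. Censored (`no_pns`) points are either substituted by
#' the reachable cap plus 1 mT/m (`censor_rule = "cap_plus_one"`, a
#' conservative lower bound) or omitted.
#'
#' @param measurements Measurement rows for a single subject and axis.
#' @param envelope Hardware envelope supplying the cap.
#' @param censor_rule `"cap_plus_one"` or `"omit"`.
#' @return An object of class `pns_subject_fit`: `ok` (logical), and when
#'   `ok`, `intercept` (mT/m), `slope` (mT/m per ms), `n_points`,
#'   `n_censored`.
#' @export
per_subject_linear_fit <- function(measurements,
                                   envelope = hardware_envelope(),
                                   censor_rule = c("cap_plus_one", "omit")) {
  censor_rule <- match.arg(censor_rule)
  m <- measurements[measurements$status != "not_tested", , drop = FALSE]
  if (length(unique(m$subject_id)) > 1 || length(unique(m$axis)) > 1) {
    stop("per_subject_linear_fit() expects one subject and one axis")
  }
  amp <- m$amplitude_mTm
  cen <- m$status == "no_pns"
  if (censor_rule == "cap_plus_one") {
    amp[cen] <- hardware_max_amplitude(m$rise_time_ms[cen], envelope) + 1
  } else {
    m <- m[!cen, , drop = FALSE]
    amp <- amp[!cen]
  }
  res <- list(subject_id = unique(measurements$subject_id),
              axis = unique(measurements$axis),
              censor_rule = censor_rule,
              n_points = nrow(m),
              n_censored = if (censor_rule == "cap_plus_one") sum(cen) else 0L)
  if (nrow(m) < 2 || length(unique(m$rise_time_ms)) < 2) {
    res$ok <- FALSE
  } else {
    cf <- coef(lm(amp ~ m$rise_time_ms))
    res$ok <- TRUE
    res$intercept <- unname(cf[1])
    res$slope <- unname(cf[2])
  }
  class(res) <- "pns_subject_fit"
  res
}

#' Per-subject linear fits for every subject on one axis
#'
#' @param cohort A `pns_cohort`.
#' @param axis Gradient axis.
#' @param z_offset Z-offset subset, cm.
#' @param ... Passed to [per_subject_linear_fit()].
#' @return Data frame with one row per subject: `subject_id`, `ok`,
#'   `intercept`, `slope`, `n_points`, `n_censored`.
#' @export
per_subject_linear_fits <- function(cohort, axis, z_offset = 0, ...) {
  stopifnot(inherits(cohort, "pns_cohort"))
  m <- cohort$measurements
  m <- m[m$axis == axis & m$z_offset_cm == z_offset, , drop = FALSE]
  out <- lapply(split(m, m$subject_id), function(mm) {
    f <- per_subject_linear_fit(mm, envelope = cohort$envelope, ...)
    data.frame(subject_id = f$subject_id, ok = f$ok,
               intercept = if (f$ok) f$intercept else NA_real_,
               slope = if (f$ok) f$slope else NA_real_,
               n_points = f$n_points, n_censored = f$n_censored)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Export threshold curves as a plain table
#'
#' @param curves A list of `pns_threshold_curve` objects.
#' @param path Optional CSV output path.
#' @return Data frame `axis,context,dGmin_mTm,SRmin_mTm_per_ms`.
#' @export
curve_table <- function(curves, path = NULL) {
  if (inherits(curves, "pns_threshold_curve")) curves <- list(curves)
  df <- do.call(rbind, lapply(curves, function(cu) {
    ctx <- if (length(cu$context)) {
      paste(names(cu$context), unlist(cu$context), sep = "=", collapse = ";")
    } else ""
    data.frame(axis = if (is.null(cu$axis)) NA_character_ else cu$axis,
               context = ctx, dGmin_mTm = cu$dGmin,
               SRmin_mTm_per_ms = cu$SRmin)
  }))
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  df
}
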