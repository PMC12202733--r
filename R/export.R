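#' Coefficient table of a fitted model
#'
#' @param fit A `pns_logit`.
#' @param path Optional CSV output path.
#' @return Data frame with one row per coefficient: estimate, standard
#'   error, Wald z and two-sided p-value.
#' @export
coefficient_table <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "pns_logit"))
  df <- data.frame(term = names(fit$coefficients),
                   estimate = unname(fit$coefficients),
                   se = unname(fit$se), z = unname(fit$z),
                   p_value = unname(fit$p_value))
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  df
}

#' Export a fit report as JSON
#'
#' Writes coefficients, standard errors, p-values, covariate centers, fit
#' options and convergence diagnostics.
#'
#' @param fit A `pns_logit`/`pns_model`.
#' @param path Output path.
#' @return Invisibly, the report list.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "pns_logit"))
  rpt <- list(axis = fit$axis,
              coefficients = as.list(fit$coefficients),
              se = as.list(fit$se),
              p_values = as.list(fit$p_value),
              centers = if (is.null(fit$spec)) list() else
                as.list(fit$spec$centers),
              loglik = fit$loglik, n = fit$n, ridge = fit$ridge,
              converged = fit$converged, iterations = fit$iterations,
              max_score = fit$max_score)
  jsonlite::write_json(rpt, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(rpt)
}

#' Export expanded observations as CSV
#'
#' @param observations A `pns_observations` data frame.
#' @param path Output path.
#' @return Invisibly, the observations.
#' @export
write_observations <- function(observations, path) {
  cols <- c("axis", "rise_time_ms", "amplitude_mTm", "response", "weight",
            "subject_id", "age_years", "sex_code", "z_offset_cm")
  write.csv(observations[cols], path, row.names = FALSE)
  invisible(observations)
}
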