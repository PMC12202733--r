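#' Expand censored threshold measurements into binary observations
#'
#' Converts each per-subject threshold (or censored "no PNS" entry) into
#' binary stimulated/not-stimulated observations for the logistic
#' regression. Two constructions are available:
#'
#' * `mode = "grid"` (default): every amplitude level on the protocol's
#'   coarse grid up to the reachable cap (plus the recorded threshold and
#'   its sub-threshold bracket point) becomes one observation, stimulating
#'   iff the level is at or above the subject's threshold; a censored
#'   (`no_pns`) row contributes zeros on the whole grid. The fitted
#'   probability then estimates the population threshold distribution
#'   function, so the 50% contour is the population median threshold --
#'   the standard conversion of staircase threshold data to a
#'   dose-response fit.
#' * `mode = "bracket"`: a minimal two-point construction. Each threshold
#'   `g` yields a supra-threshold observation `(g, S = 1)` and a
#'   sub-threshold observation `(g - fine_step, S = 0)` (omitted when
#'   non-positive); a `no_pns` row yields a single `(cap, S = 0)`. With
#'   censoring concentrated at high amplitudes this construction can
#'   produce a non-increasing amplitude response on heavily censored
#'   cohorts; it is kept for sensitivity analysis.
#'
#' `not_tested` rows yield nothing in either mode.
#'
#' @param cohort A `pns_cohort` (subject covariates are joined onto the
#'   observations).
#' @param protocol A [protocol_config()] supplying the amplitude grids.
#' @param envelope Hardware envelope used for the reachable cap; defaults
#'   to the cohort's validation envelope.
#' @param mode `"grid"` or `"bracket"`.
#' @param include_censored_zeros Include `no_pns` rows as `S = 0`
#'   observations (default `TRUE`); excluding them biases population
#'   thresholds downward.
#' @return A data frame of class `pns_observations`: columns `subject_id`,
#'   `axis`, `z_offset_cm`, `rise_time_ms`, `amplitude_mTm`, `response`,
#'   `weight` (`NA` until [compute_cell_weights()]), `age_years`,
#'   `sex_code` (F = 0, M = 1).
#' @export
expand_measurements <- function(cohort, protocol = protocol_config(),
                                envelope = NULL,
                                mode = c("grid", "bracket"),
                                include_censored_zeros = TRUE) {
  stopifnot(inherits(cohort, "pns_cohort"), inherits(protocol, "pns_protocol"))
  mode <- match.arg(mode)
  if (is.null(envelope)) envelope <- cohort$envelope
  m <- cohort$measurements
  m <- m[m$status != "not_tested", , drop = FALSE]
  if (!include_censored_zeros) m <- m[m$status != "no_pns", , drop = FALSE]

  rows <- if (nrow(m) == 0) {
    list()
  } else if (mode == "bracket") {
    .expand_bracket(m, protocol, envelope)
  } else {
    .expand_grid(m, protocol, envelope)
  }
  obs <- if (length(rows)) do.call(rbind, rows) else data.frame(
    subject_id = character(), axis = character(), z_offset_cm = numeric(),
    rise_time_ms = numeric(), amplitude_mTm = numeric(), response = integer())
  obs$weight <- NA_real_
  idx <- match(obs$subject_id, cohort$subjects$subject_id)
  obs$age_years <- cohort$subjects$age_years[idx]
  obs$sex_code <- as.integer(cohort$subjects$sex[idx] == "M")
  obs <- obs[order(obs$axis, obs$rise_time_ms, obs$subject_id,
                   obs$amplitude_mTm), , drop = FALSE]
  rownames(obs) <- NULL
  class(obs) <- c("pns_observations", "data.frame")
  obs
}

#' @keywords internal
.expand_bracket <- function(m, protocol, envelope) {
  rows <- list()
  thr <- m[m$status == "threshold", , drop = FALSE]
  if (nrow(thr)) {
    sup <- data.frame(subject_id = thr$subject_id, axis = thr$axis,
                      z_offset_cm = thr$z_offset_cm,
                      rise_time_ms = thr$rise_time_ms,
                      amplitude_mTm = thr$amplitude_mTm, response = 1L)
    sub <- sup
    sub$amplitude_mTm <- thr$amplitude_mTm - protocol$fine_step
    sub$response <- 0L
    sub <- sub[sub$amplitude_mTm > 0, , drop = FALSE]
    rows <- c(rows, list(sup, sub))
  }
  cen <- m[m$status == "no_pns", , drop = FALSE]
  if (nrow(cen)) {
    rows <- c(rows, list(data.frame(
      subject_id = cen$subject_id, axis = cen$axis,
      z_offset_cm = cen$z_offset_cm, rise_time_ms = cen$rise_time_ms,
      amplitude_mTm = hardware_max_amplitude(cen$rise_time_ms, envelope),
      response = 0L)))
  }
  rows
}

#' @keywords internal
.expand_grid <- function(m, protocol, envelope) {
  lapply(seq_len(nrow(m)), function(i) {
    tau <- m$rise_time_ms[i]
    cap <- hardware_max_amplitude(tau, envelope)
    lv <- seq(protocol$coarse_step, cap, by = protocol$coarse_step)
    if (!length(lv) || lv[length(lv)] < cap) lv <- c(lv, cap)
    if (m$status[i] == "threshold") {
      g0 <- m$amplitude_mTm[i]
      bracket <- g0 - protocol$fine_step
      lv <- sort(unique(c(lv, g0, if (bracket > 0) bracket)))
      s <- as.integer(lv >= g0)
    } else {
      s <- rep(0L, length(lv))
    }
    data.frame(subject_id = m$subject_id[i], axis = m$axis[i],
               z_offset_cm = m$z_offset_cm[i], rise_time_ms = tau,
               amplitude_mTm = lv, response = s)
  })
}

#' Assign per-cell fitting weights
#'
#' The fitting weight of every observation in a (axis, rise time) cell is
#' the fraction of tested subjects in that cell that stimulated, i.e.
#' `n_threshold / n_tested` (a subject counts as tested if it contributed
#' any observation to the cell). Weights lie in `[0, 1]`; a cell in which
#' nobody stimulated gets weight 0 and contributes nothing to a fit.
#'
#' @param observations Output of [expand_measurements()].
#' @param by Grouping columns defining a cell. The default follows the
#'   per-rise-time, per-axis stimulated fraction; add `"z_offset_cm"` for
#'   per-offset cells in pooled multi-position data.
#' @param scheme `"cell_fraction"` (default) or `"uniform"` (all weights 1,
#'   for sensitivity analysis).
#' @return The observations with `weight` filled in.
#' @export
compute_cell_weights <- function(observations,
                                 by = c("axis", "rise_time_ms"),
                                 scheme = c("cell_fraction", "uniform")) {
  scheme <- match.arg(scheme)
  stopifnot(all(by %in% names(observations)))
  if (nrow(observations) == 0) {
    warning("no observations; nothing to weight")
    return(observations)
  }
  if (scheme == "uniform") {
    observations$weight <- 1
    return(observations)
  }
  key <- interaction(observations[by], drop = TRUE)
  for (cell in levels(key)) {
    rows <- which(key == cell)
    tested <- unique(observations$subject_id[rows])
    stim <- unique(observations$subject_id[rows][
      observations$response[rows] == 1L])
    observations$weight[rows] <- length(stim) / length(tested)
  }
  observations
}
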