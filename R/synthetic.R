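#' Synthetic cohort configuration
#'
#' Describes a simulated population of subjects with latent linear threshold
#' curves `t*(tau, z) = a_i + b_i * tau + z_effect * z`, covariate effects
#' on the intercept (age, sex), and the titration protocol through which the
#' latent thresholds are observed (with censoring at the hardware cap).
#'
#' Population defaults place the cohort in the measured range: intercepts
#' around 60 mT/m and slopes around 150 mT/m/ms put latent thresholds at
#' 0.1-0.5 ms rise times in roughly the 50-200 mT/m band of the bundled
#' tables; the Z-offset effect defaults to 20 mT/m per cm and the age effect
#' to +0.5 mT/m per year (thresholds rise with age).
#'
#' @param n_subjects Number of subjects.
#' @param seed RNG seed; the generated cohort is a deterministic function
#'   of the config.
#' @param dgmin_mean,dgmin_sd Population intercept distribution, mT/m.
#' @param srmin_mean,srmin_sd Population slope distribution, mT/m/ms.
#' @param age_mean,age_sd Age distribution, years (clamped to `[18, 100]`).
#' @param age_effect Intercept shift per year of age, mT/m.
#' @param sex_effect Intercept shift for males (code 1), mT/m.
#' @param z_effect Threshold shift per cm Z-offset toward feet, mT/m.
#' @param axes Gradient axes to test.
#' @param tau_grid Rise-time grid, ms.
#' @param z_offsets Z-offsets tested, cm.
#' @param response `"deterministic"` (subject responds iff amplitude >=
#'   latent threshold) or `"logistic"` (response probability
#'   `plogis(kappa * (dG - t*))` per presentation).
#' @param kappa Logistic response slope, per mT/m.
#' @param protocol A [protocol_config()].
#' @param envelope A [hardware_envelope()].
#' @return An object of class `pns_sim_config`.
#' @export
cohort_sim_config <- function(n_subjects = 30, seed = 1,
                              dgmin_mean = 60, dgmin_sd = 15,
                              srmin_mean = 150, srmin_sd = 40,
                              age_mean = 55, age_sd = 15,
                              age_effect = 0.5, sex_effect = 0,
                              z_effect = 20,
                              axes = "x",
                              tau_grid = c(0.1, 0.22, 0.3, 0.5),
                              z_offsets = 0,
                              response = c("deterministic", "logistic"),
                              kappa = 2,
                              protocol = protocol_config(),
                              envelope = hardware_envelope()) {
  response <- match.arg(response)
  stopifnot(n_subjects >= 1, dgmin_sd >= 0, srmin_sd >= 0, age_sd >= 0,
            all(tau_grid > 0), all(axes %in% .axes),
            inherits(protocol, "pns_protocol"),
            inherits(envelope, "pns_envelope"))
  if (response == "logistic" && kappa <= 0) {
    stop("kappa must be positive for the logistic response model")
  }
  structure(list(n_subjects = n_subjects, seed = seed,
                 dgmin_mean = dgmin_mean, dgmin_sd = dgmin_sd,
                 srmin_mean = srmin_mean, srmin_sd = srmin_sd,
                 age_mean = age_mean, age_sd = age_sd,
                 age_effect = age_effect, sex_effect = sex_effect,
                 z_effect = z_effect, axes = axes, tau_grid = tau_grid,
                 z_offsets = z_offsets, response = response, kappa = kappa,
                 protocol = protocol, envelope = envelope),
            class = "pns_sim_config")
}

#' Read a simulator configuration from YAML or JSON
#'
#' Scalar fields override the [cohort_sim_config()] defaults; `protocol`
#' and `envelope` may be given as nested maps.
#'
#' @param path A `.yaml`/`.yml` (requires the yaml package) or `.json`
#'   file.
#' @return A `pns_sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required to read YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$protocol)) raw$protocol <- do.call(protocol_config,
                                                     raw$protocol)
  if (!is.null(raw$envelope)) raw$envelope <- do.call(hardware_envelope,
                                                     raw$envelope)
  do.call(cohort_sim_config, raw)
}

#' Draw the latent subject population
#'
#' Per subject: age from a clamped normal, sex Bernoulli(1/2), latent
#' intercept `a_i ~ N(dgmin_mean + age_effect * (age - age_mean) +
#' sex_effect * sex, dgmin_sd)` and slope `b_i ~ N(srmin_mean, srmin_sd)`,
#' both truncated to be positive.
#'
#' @param config A [cohort_sim_config()].
#' @return Data frame `subject_id, sex, age_years, a, b` (one row per
#'   subject); deterministic given `config$seed`.
#' @export
sample_population <- function(config) {
  stopifnot(inherits(config, "pns_sim_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  age <- pmin(pmax(round(rnorm(n, config$age_mean, config$age_sd)), 18), 100)
  sex <- ifelse(runif(n) < 0.5, "M", "F")
  mu_a <- config$dgmin_mean + config$age_effect * (age - config$age_mean) +
    config$sex_effect * (sex == "M")
  rtnorm <- function(mu, sd) {
    if (sd == 0) return(pmax(mu, .Machine$double.eps))
    x <- rnorm(length(mu), mu, sd)
    for (i in seq_len(100)) {
      bad <- x <= 0
      if (!any(bad)) break
      x[bad] <- rnorm(sum(bad), mu[bad], sd)
    }
    pmax(x, .Machine$double.eps)
  }
  a <- rtnorm(mu_a, config$dgmin_sd)
  b <- rtnorm(rep(config$srmin_mean, n), config$srmin_sd)
  data.frame(subject_id = as.character(seq_len(n)), sex = sex,
             age_years = age, a = a, b = b)
}

#' Latent threshold of a simulated subject
#'
#' @param subject One row of [sample_population()] output (or any list with
#'   `a` and `b`).
#' @param tau Rise time, ms.
#' @param z_offset Z-offset, cm.
#' @param config A [cohort_sim_config()] supplying `z_effect`.
#' @return Latent threshold `a + b * tau + z_effect * z_offset`, mT/m.
#' @export
latent_threshold <- function(subject, tau, z_offset = 0, config) {
  stopifnot(tau > 0)
  subject$a + subject$b * tau + config$z_effect * z_offset
}

#' Simulate one titration run
#'
#' Amplitude ascends in coarse steps (with the reachable cap appended as a
#' final test level) until the subject first responds; the onset is then
#' bracketed from below, ascending in fine steps from one fine step above
#' the last non-stimulating coarse level. The recorded threshold is the
#' first fine-grid amplitude that stimulates. If no reachable level
#' stimulates the run is censored (`no_pns`). In deterministic mode a level
#' stimulates iff it is at or above the latent threshold, so the recorded
#' value overshoots the latent threshold by less than one fine step and
#' censoring occurs exactly when the latent threshold exceeds the cap.
#'
#' @param t_star Latent threshold, mT/m (> 0).
#' @param tau Rise time, ms.
#' @param protocol A [protocol_config()].
#' @param envelope A [hardware_envelope()].
#' @param response `"deterministic"` or `"logistic"`.
#' @param kappa Logistic response slope, per mT/m (logistic mode).
#' @return List with `status` (`"threshold"` or `"no_pns"`) and
#'   `amplitude` (mT/m or `NA`).
#' @export
simulate_titration <- function(t_star, tau, protocol = protocol_config(),
                               envelope = hardware_envelope(),
                               response = c("deterministic", "logistic"),
                               kappa = 2) {
  response <- match.arg(response)
  stopifnot(t_star > 0, tau > 0)
  cap <- hardware_max_amplitude(tau, envelope)
  responds <- if (response == "deterministic") {
    function(g) g >= t_star
  } else {
    function(g) runif(1) < plogis(kappa * (g - t_star))
  }
  coarse <- seq(protocol$coarse_step, cap, by = protocol$coarse_step)
  if (!length(coarse) || coarse[length(coarse)] < cap) {
    coarse <- c(coarse, cap)
  }
  hit <- NA_integer_
  for (i in seq_along(coarse)) {
    if (responds(coarse[i])) {
      hit <- i
      break
    }
  }
  if (is.na(hit)) {
    return(list(status = "no_pns", amplitude = NA_real_))
  }
  lower <- if (hit == 1) 0 else coarse[hit - 1]
  fine <- seq(lower + protocol$fine_step, coarse[hit],
              by = protocol$fine_step)
  if (fine[length(fine)] < coarse[hit]) fine <- c(fine, coarse[hit])
  for (g in fine) {
    if (responds(g)) {
      return(list(status = "threshold", amplitude = g))
    }
  }
  # logistic mode only: nothing re-stimulated during refinement; fall back
  # to the coarse level that did stimulate
  list(status = "threshold", amplitude = coarse[hit])
}

#' Simulate a full cohort through the titration protocol
#'
#' @param config A [cohort_sim_config()].
#' @return A `pns_cohort` whose `subjects`/`measurements` tables are in the
#'   fixture format (site `"synthetic"`), with an extra element `truth`:
#'   the latent population table plus the generating config. Byte-identical
#'   given the same config.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "pns_sim_config"))
  pop <- sample_population(config)  # also seeds the RNG for titration
  rows <- vector("list",
                 nrow(pop) * length(config$axes) * length(config$z_offsets) *
                   length(config$tau_grid))
  k <- 0
  for (i in seq_len(nrow(pop))) {
    for (ax in config$axes) {
      for (z in config$z_offsets) {
        for (tau in config$tau_grid) {
          t_star <- latent_threshold(pop[i, ], tau, z, config)
          r <- simulate_titration(t_star, tau, config$protocol,
                                  config$envelope, config$response,
                                  config$kappa)
          k <- k + 1
          rows[[k]] <- data.frame(
            subject_id = pop$subject_id[i], axis = ax, z_offset_cm = z,
            rise_time_ms = tau, status = r$status,
            amplitude_mTm = r$amplitude, location = "")
        }
      }
    }
  }
  subjects <- data.frame(subject_id = pop$subject_id, site = "synthetic",
                         sex = pop$sex, age_years = pop$age_years,
                         height_cm = NA_real_, weight_kg = NA_real_)
  cohort <- structure(list(subjects = subjects,
                           measurements = do.call(rbind, rows),
                           envelope = config$envelope,
                           truth = list(population = pop, config = config)),
                      class = "pns_cohort")
  validate_subjects(cohort$subjects)
  validate_measurements(cohort$measurements, cohort$subjects,
                        config$envelope)
  cohort
}

#' Write a simulated cohort as fixture-format tables plus a manifest
#'
#' Produces `subjects.csv` and `measurements.csv` (parsable by
#' [read_cohort()]) and `manifest.json` recording the seed, the full
#' config and the latent truth table for recovery scoring.
#'
#' @param config A [cohort_sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the simulated `pns_cohort`.
#' @export
generate_cohort_tables <- function(config, dir) {
  cohort <- simulate_cohort(config)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_cohort(cohort, file.path(dir, "subjects.csv"),
               file.path(dir, "measurements.csv"))
  manifest <- list(seed = config$seed,
                   config = unclass(config),
                   latent_population = cohort$truth$population)
  manifest$config$protocol <- unclass(manifest$config$protocol)
  manifest$config$envelope <- unclass(manifest$config$envelope)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(cohort)
}
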