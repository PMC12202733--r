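#' @keywords internal
.site_tau_grids <- list(
  berkeley = c(0.1, 0.22, 0.3, 0.5),
  erlangen = seq(0.1, 0.8, by = 0.1)
)

.axes <- c("x", "y", "z")
.statuses <- c("threshold", "no_pns", "not_tested")

#' Default per-site validation envelopes
#'
#' The scanner envelope is 900 mT/m/ms and 200 mT/m. Factory acceptance
#' testing ramped slightly faster than the scanner's operating slew limit
#' (printed thresholds of 91 mT/m at 0.1 ms and up to 195 mT/m at 0.2 ms
#' imply ramps up to ~975 mT/m/ms), so the validation envelope for the
#' `erlangen` site allows 1000 mT/m/ms.
#'
#' @param site `"berkeley"` or `"erlangen"` (anything else gets the scanner
#'   envelope).
#' @return A [hardware_envelope()].
#' @export
site_envelope <- function(site) {
  if (identical(site, "erlangen")) {
    hardware_envelope(slew_max = 1000, g_max = 200)
  } else {
    hardware_envelope()
  }
}

#' Read a censored threshold cohort
#'
#' Reads a subjects table and a measurements table (one row per subject x
#' axis x rise time) and validates both. Measurement status is one of
#' `threshold` (an onset amplitude was recorded), `no_pns` (no stimulation up
#' to the reachable amplitude cap; censored) or `not_tested`.
#'
#' @param subjects_path CSV with columns
#'   `subject_id,site,sex,age_years,height_cm,weight_kg` (empty string for a
#'   missing optional field).
#' @param measurements_path CSV with columns
#'   `subject_id,axis,z_offset_cm,rise_time_ms,status,amplitude_mTm,location`;
#'   `amplitude_mTm` must be present iff `status == "threshold"`.
#' @param envelope Validation envelope; defaults to the site envelope of the
#'   subjects table (see [site_envelope()]) when all subjects share a site.
#' @param cap_slack Amplitude validation slack above the envelope cap, mT/m.
#'   Measured onsets can land one refinement step above the nominal
#'   slew-limited level (e.g. 92 mT/m recorded at a 0.1-ms rise time whose
#'   nominal cap is 90), so the default slack is one fine step. Censoring
#'   caps are never slackened.
#' @return An object of class `pns_cohort`: a list with data frames
#'   `subjects` and `measurements` and the validation `envelope`.
#' @seealso [read_site_fixture()] for the bundled tables.
#' @export
read_cohort <- function(subjects_path, measurements_path, envelope = NULL,
                        cap_slack = 2) {
  for (p in c(subjects_path, measurements_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  subjects <- read.csv(subjects_path, colClasses = c(
    subject_id = "character", site = "character", sex = "character",
    age_years = "numeric", height_cm = "numeric", weight_kg = "numeric"))
  measurements <- read.csv(measurements_path, colClasses = c(
    subject_id = "character", axis = "character", z_offset_cm = "numeric",
    rise_time_ms = "numeric", status = "character",
    amplitude_mTm = "numeric", location = "character"))
  if (is.null(envelope)) {
    sites <- unique(subjects$site)
    envelope <- site_envelope(if (length(sites) == 1) sites else "")
  }
  validate_subjects(subjects)
  validate_measurements(measurements, subjects, envelope, cap_slack)
  structure(list(subjects = subjects, measurements = measurements,
                 envelope = envelope),
            class = "pns_cohort")
}

#' @keywords internal
validate_subjects <- function(subjects) {
  need <- c("subject_id", "site", "sex", "age_years", "height_cm", "weight_kg")
  miss <- setdiff(need, names(subjects))
  if (length(miss)) stop("subjects table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(subjects[c("site", "subject_id")])) {
    stop("duplicate subject_id within site")
  }
  bad <- which(!subjects$sex %in% c("M", "F"))
  if (length(bad)) stop("subjects row ", bad[1], ": sex must be M or F")
  bad <- which(is.na(subjects$age_years) | subjects$age_years < 18 |
                 subjects$age_years > 100)
  if (length(bad)) stop("subjects row ", bad[1],
                        ": age_years must lie in [18, 100]")
  for (col in c("height_cm", "weight_kg")) {
    bad <- which(!is.na(subjects[[col]]) & subjects[[col]] <= 0)
    if (length(bad)) stop("subjects row ", bad[1], ": ", col,
                          " must be positive when present")
  }
  invisible(subjects)
}

#' @keywords internal
validate_measurements <- function(measurements, subjects, envelope,
                                  cap_slack = 0) {
  need <- c("subject_id", "axis", "z_offset_cm", "rise_time_ms", "status",
            "amplitude_mTm", "location")
  miss <- setdiff(need, names(measurements))
  if (length(miss)) stop("measurements table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(measurements) == 0) return(invisible(measurements))
  bad <- which(!measurements$subject_id %in% subjects$subject_id)
  if (length(bad)) stop("measurements row ", bad[1],
                        ": unknown subject_id ",
                        measurements$subject_id[bad[1]])
  bad <- which(!measurements$axis %in% .axes)
  if (length(bad)) stop("measurements row ", bad[1],
                        ": axis must be one of x, y, z")
  bad <- which(!measurements$status %in% .statuses)
  if (length(bad)) stop("measurements row ", bad[1],
                        ": invalid status ", measurements$status[bad[1]])
  bad <- which(is.na(measurements$rise_time_ms) |
                 measurements$rise_time_ms <= 0)
  if (length(bad)) stop("measurements row ", bad[1],
                        ": rise_time_ms must be positive")
  # rise-time grid membership for the two measured sites
  site_of <- setNames(subjects$site, subjects$subject_id)
  msite <- site_of[measurements$subject_id]
  for (s in intersect(unique(msite), names(.site_tau_grids))) {
    rows <- which(msite == s)
    ok <- sapply(measurements$rise_time_ms[rows], function(t) {
      any(abs(t - .site_tau_grids[[s]]) < 1e-9)
    })
    if (!all(ok)) {
      r <- rows[which(!ok)[1]]
      stop("measurements row ", r, ": rise time ",
           measurements$rise_time_ms[r], " ms not on the ", s, " grid")
    }
  }
  is_thr <- measurements$status == "threshold"
  bad <- which(is_thr & (is.na(measurements$amplitude_mTm) |
                           measurements$amplitude_mTm <= 0))
  if (length(bad)) stop("measurements row ", bad[1],
                        ": threshold rows need a positive amplitude_mTm")
  bad <- which(!is_thr & !is.na(measurements$amplitude_mTm))
  if (length(bad)) stop("measurements row ", bad[1], ": status ",
                        measurements$status[bad[1]],
                        " must not carry an amplitude")
  cap <- hardware_max_amplitude(measurements$rise_time_ms[is_thr], envelope)
  over <- which(measurements$amplitude_mTm[is_thr] > cap + cap_slack + 1e-9)
  if (length(over)) {
    r <- which(is_thr)[over[1]]
    stop("measurements row ", r, ": amplitude ",
         measurements$amplitude_mTm[r],
         " mT/m exceeds the hardware cap ", round(cap[over[1]], 3),
         " mT/m at rise time ", measurements$rise_time_ms[r], " ms")
  }
  invisible(measurements)
}

#' Write a cohort back to the CSV fixture format
#'
#' Inverse of [read_cohort()]: `write_cohort()` followed by [read_cohort()]
#' reproduces the tables field-for-field.
#'
#' @param cohort A `pns_cohort`.
#' @param subjects_path,measurements_path Output CSV paths.
#' @return Invisibly, the cohort.
#' @export
write_cohort <- function(cohort, subjects_path, measurements_path) {
  stopifnot(inherits(cohort, "pns_cohort"))
  write.csv(cohort$subjects, subjects_path, row.names = FALSE, na = "")
  write.csv(cohort$measurements, measurements_path, row.names = FALSE,
            na = "")
  invisible(cohort)
}

#' Summarize a cohort's subject table
#'
#' Means and standard deviations are computed over non-missing values only;
#' the count of contributing values is reported alongside each.
#'
#' @param subjects A subjects data frame, or a `pns_cohort`.
#' @return A one-row data frame with `n`, `n_male`, `n_female`, and
#'   mean/SD/count triples for age and weight.
#' @examples
#' coh <- read_site_fixture("berkeley")
#' summarize_cohort(coh) # mean age 52.2 y, mean weight 74.0 kg over 28
#' @export
summarize_cohort <- function(subjects) {
  if (inherits(subjects, "pns_cohort")) subjects <- subjects$subjects
  if (!is.data.frame(subjects) || nrow(subjects) == 0) {
    stop("summarize_cohort() needs a non-empty subjects table")
  }
  msd <- function(x) {
    x <- x[!is.na(x)]
    c(mean = if (length(x)) mean(x) else NA_real_,
      sd = if (length(x) > 1) sd(x) else NA_real_,
      n = length(x))
  }
  a <- msd(subjects$age_years)
  w <- msd(subjects$weight_kg)
  data.frame(n = nrow(subjects),
             n_male = sum(subjects$sex == "M"),
             n_female = sum(subjects$sex == "F"),
             age_mean = a[["mean"]], age_sd = a[["sd"]], age_n = a[["n"]],
             weight_mean = w[["mean"]], weight_sd = w[["sd"]],
             weight_n = w[["n"]])
}

#' Path to a bundled fixture file
#'
#' @param file File name under the package's `extdata` directory.
#' @return Absolute path.
#' @export
pns_fixture <- function(file) {
  p <- system.file("extdata", file, package = "pnsthresh", mustWork = FALSE)
  if (identical(p, "")) stop("no bundled fixture named ", file)
  p
}

#' Read one of the bundled measured cohorts
#'
#' `"berkeley"` is the in-scanner cohort (29 subjects, isocenter, rise times
#' 0.1/0.22/0.3/0.5 ms); `"erlangen"` is the factory cohort (32 subjects,
#' rise times 0.1-0.8 ms).
#'
#' @param site `"berkeley"` or `"erlangen"`.
#' @return A `pns_cohort`.
#' @export
read_site_fixture <- function(site = c("berkeley", "erlangen")) {
  site <- match.arg(site)
  files <- switch(site,
    berkeley = c("berkeley_subjects.csv", "berkeley_iso_measurements.csv"),
    erlangen = c("erlangen_subjects.csv", "erlangen_measurements.csv"))
  read_cohort(pns_fixture(files[1]), pns_fixture(files[2]),
              envelope = site_envelope(site))
}

#' @export
print.pns_cohort <- function(x, ...) {
  tab <- table(x$measurements$status)
  cat("PNS cohort: ", nrow(x$subjects), " subjects, ",
      nrow(x$measurements), " measurements (",
      paste(names(tab), as.integer(tab), sep = "=", collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}
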