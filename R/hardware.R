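#' Hardware envelope of a gradient system
#'
#' The amplitude reachable at a rise time `tau` is limited by the slew rate
#' (`slew_max * tau`) and by the maximum gradient amplitude `g_max`. `g_nom`
#' is the nominal (thermally sustainable) amplitude limit used for EPI
#' planning; it never constrains threshold validation.
#'
#' @param slew_max Maximum slew rate, mT/m/ms.
#' @param g_max Maximum gradient amplitude, mT/m.
#' @param g_nom Nominal usable amplitude for sustained EPI readouts, mT/m.
#' @return An object of class `pns_envelope`.
#' @examples
#' env <- hardware_envelope()
#' hardware_max_amplitude(0.1, env) # 90 mT/m, slew-limited
#' @export
hardware_envelope <- function(slew_max = 900, g_max = 200, g_nom = 85) {
  stopifnot(is.numeric(slew_max), slew_max > 0,
            is.numeric(g_max), g_max > 0,
            is.numeric(g_nom), g_nom > 0)
  if (g_nom > g_max) {
    stop("g_nom must not exceed g_max")
  }
  structure(list(slew_max = slew_max, g_max = g_max, g_nom = g_nom),
            class = "pns_envelope")
}

#' Titration protocol configuration
#'
#' Amplitude is increased in coarse steps until the subject first reports
#' stimulation, then refined in fine steps to bracket the onset. The pulse
#' train description (`n_pulses`, `plateau_us`) and the note that the
#' alternating-polarity stimulus spans `2 * dG` over `2 * tau` are metadata
#' only: all amplitudes in this package are zero-to-peak and the doubling is
#' never applied as a multiplier.
#'
#' @param coarse_step Coarse amplitude increment, mT/m.
#' @param fine_step Fine refinement increment, mT/m; must divide
#'   `coarse_step`.
#' @param n_pulses Number of alternating bipolar trapezoidal pulses per
#'   stimulation train (metadata).
#' @param plateau_us Plateau duration of each trapezoid, microseconds
#'   (metadata).
#' @return An object of class `pns_protocol`.
#' @export
protocol_config <- function(coarse_step = 20, fine_step = 2,
                            n_pulses = 128, plateau_us = 500) {
  stopifnot(coarse_step > 0, fine_step > 0)
  if (coarse_step %% fine_step != 0) {
    stop("fine_step must divide coarse_step")
  }
  structure(list(coarse_step = coarse_step, fine_step = fine_step,
                 n_pulses = n_pulses, plateau_us = plateau_us),
            class = "pns_protocol")
}

#' Maximum reachable amplitude at a given rise time
#'
#' @param tau Rise time(s), ms; strictly positive.
#' @param envelope A [hardware_envelope()].
#' @return Amplitude cap `min(g_max, slew_max * tau)` in mT/m, vectorized
#'   over `tau`.
#' @examples
#' hardware_max_amplitude(c(0.1, 0.5)) # 90, 200
#' @export
hardware_max_amplitude <- function(tau, envelope = hardware_envelope()) {
  stopifnot(inherits(envelope, "pns_envelope"), is.numeric(tau))
  if (any(tau <= 0)) {
    stop("rise time must be strictly positive")
  }
  pmin(envelope$g_max, envelope$slew_max * tau)
}
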