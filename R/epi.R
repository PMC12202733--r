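#' EPI readout configuration
#'
#' @param resolution_mm Isotropic in-plane resolution, mm.
#' @param gammabar_MHz_per_T Reduced gyromagnetic ratio (gamma / 2 pi),
#'   MHz per tesla; proton by default.
#' @param envelope A [hardware_envelope()].
#' @return An object of class `pns_epi_config` (ramp sampling is off: the
#'   readout flat-top carries the full k-space traversal).
#' @export
epi_config <- function(resolution_mm, gammabar_MHz_per_T = 42.577,
                       envelope = hardware_envelope()) {
  stopifnot(resolution_mm > 0, gammabar_MHz_per_T > 0,
            inherits(envelope, "pns_envelope"))
  structure(list(resolution_mm = resolution_mm,
                 gammabar_MHz_per_T = gammabar_MHz_per_T,
                 envelope = envelope,
                 area_mTm_ms = readout_area(resolution_mm,
                                            gammabar_MHz_per_T)),
            class = "pns_epi_config")
}

#' Gradient-time area of one EPI readout line
#'
#' The full k-space width for resolution `r` is `1 / r`; the required
#' gradient-time area `A` satisfies `gammabar * A = 1 / r`. In practical
#' units `A = 1000 / (r_mm * gammabar_MHz_per_T)` (mT/m) * ms.
#'
#' @param resolution_mm Isotropic resolution, mm.
#' @param gammabar_MHz_per_T Reduced gyromagnetic ratio, MHz/T.
#' @return Area in (mT/m) * ms.
#' @examples
#' readout_area(0.6) # ~39.14 (mT/m) ms
#' @export
readout_area <- function(resolution_mm, gammabar_MHz_per_T = 42.577) {
  if (any(resolution_mm <= 0)) stop("resolution must be positive")
  1000 / (resolution_mm * gammabar_MHz_per_T)
}

#' Echo spacing of a trapezoidal EPI readout
#'
#' With no ramp sampling, each echo needs two ramps of duration `tau` plus
#' a flat-top carrying the full readout area: `ESP = 2 tau + A / G`.
#' Slew-infeasible points (`G > slew_max * tau`) and amplitude-infeasible
#' points (`G > g_max`) return `NA`.
#'
#' @param G Gradient amplitude(s), mT/m.
#' @param tau Rise time(s), ms.
#' @param config A [epi_config()].
#' @return Echo spacing in ms (`NA` where infeasible), vectorized.
#' @export
echo_spacing <- function(G, tau, config) {
  stopifnot(inherits(config, "pns_epi_config"), all(G > 0), all(tau > 0))
  esp <- 2 * tau + config$area_mTm_ms / G
  env <- config$envelope
  esp[G > env$slew_max * tau + 1e-12 | G > env$g_max + 1e-12] <- NA_real_
  esp
}

#' Corner point of the iso-echo-spacing curves
#'
#' Along slew-limited operation (`tau = G / slew_max`) the echo spacing is
#' `2 G / SR + A / G`, minimized at `G* = sqrt(A * SR / 2)`; beyond this
#' amplitude, more gradient no longer shortens the echo spacing. The
#' returned point clips `G*` to the amplitude limit in force and
#' recomputes the echo spacing there.
#'
#' @param config A [epi_config()].
#' @param g_limit Amplitude limit to clip against: `"g_max"` (default),
#'   `"g_nom"`, or a number in mT/m; `NULL` for the unconstrained
#'   minimizer.
#' @return List with `G` (mT/m), `tau` (ms), `esp` (ms) and `clipped`
#'   (logical).
#' @examples
#' corner_point(epi_config(0.6), g_limit = NULL) # G* ~ 132.7, ESP ~ 0.590
#' corner_point(epi_config(0.6), g_limit = "g_nom") # ESP ~ 0.649 at 85
#' @export
corner_point <- function(config, g_limit = "g_max") {
  stopifnot(inherits(config, "pns_epi_config"))
  env <- config$envelope
  g_star <- sqrt(config$area_mTm_ms * env$slew_max / 2)
  lim <- if (is.null(g_limit)) {
    Inf
  } else if (is.character(g_limit)) {
    env[[match.arg(g_limit, c("g_max", "g_nom"))]]
  } else {
    g_limit
  }
  g <- min(g_star, lim)
  tau <- g / env$slew_max
  list(G = g, tau = tau, esp = 2 * tau + config$area_mTm_ms / g,
       clipped = g < g_star)
}

#' PNS-feasible echo-spacing region
#'
#' Evaluates echo spacing on a (amplitude, rise time) grid and flags each
#' point for slew feasibility, amplitude feasibility and PNS feasibility
#' (amplitude at or below the threshold curve at that rise time). The
#' attached summary reports the minimum echo spacing over fully feasible
#' points and whether the PNS constraint pushes it above the hardware
#' corner value.
#'
#' @param curve A [threshold_curve()].
#' @param config A [epi_config()].
#' @param g_grid Amplitudes to scan, mT/m.
#' @param tau_grid Rise times to scan, ms.
#' @param g_limit Amplitude limit in force (as in [corner_point()]).
#' @return Data frame `G_mTm, tau_ms, esp_ms, slew_ok, amp_ok, pns_ok`
#'   with a `summary` attribute (`min_esp_pns`, `min_esp_hw`,
#'   `pns_limited`).
#' @export
pns_feasible_region <- function(curve, config,
                                g_grid = seq(5, 200, by = 1),
                                tau_grid = seq(0.01, 1, by = 0.005),
                                g_limit = "g_max") {
  stopifnot(inherits(curve, "pns_threshold_curve"),
            inherits(config, "pns_epi_config"))
  env <- config$envelope
  lim <- if (is.character(g_limit)) {
    env[[match.arg(g_limit, c("g_max", "g_nom"))]]
  } else {
    g_limit
  }
  grid <- expand.grid(G_mTm = g_grid, tau_ms = tau_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$esp_ms <- 2 * grid$tau_ms + config$area_mTm_ms / grid$G_mTm
  grid$slew_ok <- grid$G_mTm <= env$slew_max * grid$tau_ms + 1e-12
  grid$amp_ok <- grid$G_mTm <= lim + 1e-12
  grid$pns_ok <- grid$G_mTm <= threshold_at(curve, grid$tau_ms) + 1e-12
  hw <- grid$slew_ok & grid$amp_ok
  all_ok <- hw & grid$pns_ok
  min_esp_hw <- if (any(hw)) min(grid$esp_ms[hw]) else NA_real_
  min_esp_pns <- if (any(all_ok)) min(grid$esp_ms[all_ok]) else NA_real_
  attr(grid, "summary") <- list(
    min_esp_hw = min_esp_hw, min_esp_pns = min_esp_pns,
    pns_limited = isTRUE(min_esp_pns > min_esp_hw + 1e-12) ||
      is.na(min_esp_pns))
  grid
}
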