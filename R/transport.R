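## Bend-magnet energy selection and steering-coil phase-space transform.

.ME_C2 <- 0.511  # electron rest energy, MeV

.momentum <- function(E) sqrt((E + .ME_C2)^2 - .ME_C2^2)  # MeV/c

#' Calibrate the bend-magnet coil constant
#'
#' Solves the single-unknown condition that stepping the pass-through energy
#' from 6 to 10 MeV requires a 40 A coil increment (the 10 A/MeV
#' characteristic of the bend): `k2 = (p(10) - p(6)) / 40`, where `p(E)` is
#' the relativistic momentum for kinetic energy `E`.
#'
#' @return Momentum per unit coil current, MeV/A (about 0.1002).
#' @export
calibrate_k2 <- function() {
  (.momentum(10) - .momentum(6)) / 40
}

#' Bend-magnet parameters
#'
#' @param k2 Momentum selected per unit coil current, MeV/A; default from
#'   [calibrate_k2()].
#' @param acceptance_halfwidth Half-width of the energy acceptance window as
#'   a fraction of the set-point energy (default 1.5%).
#' @return An object of class `bend_params`.
#' @export
bend_params <- function(k2 = calibrate_k2(), acceptance_halfwidth = 0.015) {
  stopifnot(k2 > 0, acceptance_halfwidth > 0, acceptance_halfwidth < 0.2)
  structure(list(k2 = k2, acceptance_halfwidth = acceptance_halfwidth),
            class = "bend_params")
}

#' Bend-magnet set-point energy
#'
#' Kinetic energy selected by the solenoidal bend at a given coil current:
#' `E = sqrt((k2 I)^2 + (me c^2)^2) - me c^2`.
#'
#' @param coil_current Coil current, A (non-negative, vectorized).
#' @param params A [bend_params()].
#' @return Set-point kinetic energy, MeV.
#' @export
setpoint_energy <- function(coil_current, params = bend_params()) {
  if (any(coil_current < 0)) stop("bend coil current must be non-negative")
  sqrt((params$k2 * coil_current)^2 + .ME_C2^2) - .ME_C2
}

#' Coil current selecting a given energy (inverse of [setpoint_energy()])
#'
#' @param energy Kinetic energy, MeV (non-negative).
#' @param params A [bend_params()].
#' @return Coil current, A.
#' @export
bend_current_for_energy <- function(energy, params = bend_params()) {
  stopifnot(all(energy >= 0))
  .momentum(energy) / params$k2
}

#' Transmit a Gaussian beam through the bend's acceptance window
#'
#' The bend admits only electrons inside `setpoint * (1 +/- w)`; the passing
#' fraction is the Gaussian probability mass in that window and the
#' transmitted mean is the truncated-Gaussian mean.
#'
#' @param spectrum An [beam_spectrum()] (`energy_spectrum`).
#' @param current_in Beam current entering the bend, mA.
#' @param setpoint Set-point energy, MeV (vectorized).
#' @param params A [bend_params()].
#' @return A list of class `transport_result` with `target_current` (mA),
#'   `transmitted_mean_energy` (MeV) and `fraction`. For vector `setpoint`
#'   each field is a vector.
#' @export
transmit <- function(spectrum, current_in, setpoint, params = bend_params()) {
  stopifnot(inherits(spectrum, "energy_spectrum"), current_in >= 0,
            all(setpoint >= 0))
  w <- params$acceptance_halfwidth
  lo <- setpoint * (1 - w)
  hi <- setpoint * (1 + w)
  mu <- spectrum$mean
  sd <- spectrum$sigma
  if (sd <= 0) {
    frac <- as.numeric(mu >= lo & mu <= hi)
    mean_t <- rep(mu, length(setpoint))
  } else {
    a <- (lo - mu) / sd
    b <- (hi - mu) / sd
    frac <- stats::pnorm(b) - stats::pnorm(a)
    mean_t <- ifelse(frac > 1e-12,
                     mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / frac,
                     setpoint)
  }
  structure(list(target_current = current_in * frac,
                 transmitted_mean_energy = mean_t,
                 fraction = frac),
            class = "transport_result")
}

#' Electron-beam phase space at the target
#'
#' Tight Gaussian spot described by its centroid position, centroid angle and
#' transverse RMS size.
#'
#' @param position Length-2 numeric, (in-plane, cross-plane) centroid, cm.
#' @param angle Length-2 numeric, centroid angle, mrad.
#' @param spot_sigma Transverse RMS spot size, cm (positive).
#' @return An object of class `phase_space`.
#' @export
phase_space <- function(position = c(0, 0), angle = c(0, 0), spot_sigma = 0.1) {
  stopifnot(length(position) == 2L, length(angle) == 2L, spot_sigma > 0)
  structure(list(position = as.numeric(position), angle = as.numeric(angle),
                 spot_sigma = spot_sigma),
            class = "phase_space")
}

#' Steering-coil parameters
#'
#' @param coil_gain Deflection per unit coil current, mrad/mA (same for the
#'   position and angle coil pairs).
#' @param drift_d Drift length between the position coils and the target, cm.
#' @return An object of class `steering_params`.
#' @export
steering_params <- function(coil_gain = 0.1, drift_d = 30) {
  stopifnot(coil_gain > 0, drift_d > 0)
  structure(list(coil_gain = coil_gain, drift_d = drift_d),
            class = "steering_params")
}

#' Apply steering coils to the beam phase space
#'
#' The position coils (closest to the waveguide exit) deflect the beam
#' upstream of a drift, so they shift both the spot position on the target
#' and its angle of incidence; the angle coils act after the drift and change
#' the angle only.
#'
#' @param upstream A [phase_space()] leaving the waveguide.
#' @param pos_coil_ma Length-2 position-coil currents (in-plane,
#'   cross-plane), mA.
#' @param ang_coil_ma Length-2 angle-coil currents, mA.
#' @param params A [steering_params()].
#' @return The [phase_space()] at the target.
#' @export
steer <- function(upstream, pos_coil_ma = c(0, 0), ang_coil_ma = c(0, 0),
                  params = steering_params()) {
  stopifnot(inherits(upstream, "phase_space"),
            length(pos_coil_ma) == 2L, length(ang_coil_ma) == 2L)
  dth_pos <- params$coil_gain * as.numeric(pos_coil_ma)  # mrad
  dth_ang <- params$coil_gain * as.numeric(ang_coil_ma)
  pos <- upstream$position + params$drift_d * (upstream$angle + dth_pos) / 1000
  ang <- upstream$angle + dth_pos + dth_ang
  phase_space(position = pos, angle = ang, spot_sigma = upstream$spot_sigma)
}
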