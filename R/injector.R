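## Electron gun (space-charge limited triode) and accelerating-waveguide
## beam loading.

#' Electron gun parameters
#'
#' Space-charge limited (Child-Langmuir) triode gun. The proportionality
#' constant and perveance are folded into one effective constant,
#' `perveance_eff`, calibrated so a 7.5 kV cathode setting with zero grid
#' bias draws 115 mA. The grid cutoff voltage is retained in the interface
#' but the presets run with zero grid bias.
#'
#' @param perveance_eff Effective perveance, mA per kV^1.5.
#' @param v_cut Grid cutoff voltage, V, below which current ceases.
#' @return An object of class `gun_params`.
#' @export
gun_params <- function(perveance_eff = 115 / 7.5^1.5, v_cut = 200) {
  stopifnot(perveance_eff > 0, v_cut > 0)
  structure(list(perveance_eff = perveance_eff, v_cut = v_cut),
            class = "gun_params")
}

#' Gun current from cathode and grid voltages
#'
#' Three-halves-power law in cathode voltage times a linear grid factor
#' `(1 - V_grid/V_cut)`, clamped at zero.
#'
#' @param cathode_kv Cathode voltage, kV (non-negative).
#' @param grid_v Grid bias, V, in `[0, v_cut]`; values beyond cutoff return
#'   0 mA with a warning.
#' @param params A [gun_params()].
#' @return Beam current injected into the waveguide, mA.
#' @export
gun_current <- function(cathode_kv, grid_v = 0, params = gun_params()) {
  if (any(cathode_kv < 0)) stop("cathode voltage must be non-negative")
  if (any(grid_v < 0)) stop("grid bias must be non-negative")
  over <- grid_v > params$v_cut
  if (any(over))
    warning("grid bias beyond cutoff voltage; gun current is zero")
  fac <- pmax(0, 1 - grid_v / params$v_cut)
  params$perveance_eff * cathode_kv^1.5 * fac
}

#' Accelerating-waveguide parameters
#'
#' @param shunt_impedance Linear accelerator shunt impedance, MOhm. The
#'   default 47.88 MOhm is the steeper of the two standing-wave load lines
#'   modelled.
#' @param energy_spread_fraction Relative RMS width of the Gaussian electron
#'   energy spectrum leaving the waveguide (dimensionless, in (0, 0.2)).
#' @return An object of class `accelerator_params`.
#' @export
accelerator_params <- function(shunt_impedance = 47.88,
                               energy_spread_fraction = 0.03) {
  stopifnot(shunt_impedance > 0,
            energy_spread_fraction > 0, energy_spread_fraction < 0.2)
  structure(list(shunt_impedance = shunt_impedance,
                 energy_spread_fraction = energy_spread_fraction),
            class = "accelerator_params")
}

#' Beam-loaded accelerating potential
#'
#' Load-line model: the no-load potential grows as the square root of the
#' klystron power delivered to the guide, and beam current depresses it
#' linearly with slope -Z/2 (beam loading). The result is floored at zero;
#' electron kinetic energy in MeV is numerically equal to the potential in MV.
#'
#' @param p_kly_mw Klystron power into the waveguide, MW.
#' @param i_acc_ma Accelerated beam current, mA.
#' @param params An [accelerator_params()].
#' @return Mean electron kinetic energy, MeV.
#' @export
loaded_energy <- function(p_kly_mw, i_acc_ma, params = accelerator_params()) {
  stopifnot(all(p_kly_mw >= 0), all(i_acc_ma >= 0))
  z <- params$shunt_impedance
  pmax(0, sqrt(p_kly_mw * z) - (i_acc_ma / 1000) * z / 2)
}

#' Gaussian electron energy spectrum
#'
#' The beam entering the bend magnet is modelled as Gaussian in energy with
#' RMS width proportional to the mean.
#'
#' @param mean_energy Mean kinetic energy, MeV (non-negative).
#' @param params An [accelerator_params()] supplying the spread fraction.
#' @return An object of class `energy_spectrum` with fields `mean` and
#'   `sigma` (MeV).
#' @export
beam_spectrum <- function(mean_energy, params = accelerator_params()) {
  stopifnot(mean_energy >= 0)
  structure(list(mean = mean_energy,
                 sigma = params$energy_spread_fraction * mean_energy),
            class = "energy_spectrum")
}
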