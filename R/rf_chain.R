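## Klystron amplifier: maximum power vs cathode voltage and saturating gain
## vs RF drive power.

#' Klystron model parameters
#'
#' The klystron's maximum output power is linear in cathode voltage over its
#' rated 100-145 kV window, and the saturating drive level is proportional to
#' cathode voltage. Default anchors: 9 MW maximum output and 67 W saturation
#' drive at the 125 kV operating voltage, with a 0.1 MW/kV slope, matching a
#' high-power medical-linac klystron.
#'
#' @param pmax_ref Maximum output power (MW) at `ref_voltage`.
#' @param pmax_slope Slope of maximum output power vs voltage, MW/kV.
#' @param ref_voltage Reference cathode voltage, kV.
#' @param pc_per_kv Saturation drive power per unit cathode voltage, W/kV.
#' @param voltage_range Rated cathode voltage window, kV.
#' @return An object of class `klystron_params`.
#' @export
klystron_params <- function(pmax_ref = 9, pmax_slope = 0.1, ref_voltage = 125,
                            pc_per_kv = 67 / 125,
                            voltage_range = c(100, 145)) {
  stopifnot(pc_per_kv > 0, length(voltage_range) == 2L,
            voltage_range[1L] < voltage_range[2L])
  p <- structure(list(pmax_ref = pmax_ref, pmax_slope = pmax_slope,
                      ref_voltage = ref_voltage, pc_per_kv = pc_per_kv,
                      voltage_range = voltage_range),
                 class = "klystron_params")
  if (any(klystron_max_power(voltage_range, p) <= 0))
    stop("maximum klystron power must be positive over the voltage range")
  p
}

.check_kly_voltage <- function(voltage, params) {
  r <- params$voltage_range
  if (any(voltage < r[1L] | voltage > r[2L]))
    stop(sprintf("klystron cathode voltage must lie in [%g, %g] kV", r[1L], r[2L]))
}

#' Maximum klystron output power vs cathode voltage
#'
#' @param voltage Cathode voltage, kV (vectorized; must lie in the rated range).
#' @param params A [klystron_params()].
#' @return Maximum output power, MW.
#' @export
klystron_max_power <- function(voltage, params = klystron_params()) {
  .check_kly_voltage(voltage, params)
  params$pmax_ref + params$pmax_slope * (voltage - params$ref_voltage)
}

#' Saturation drive power vs cathode voltage
#'
#' The critical RF drive level at which the klystron output saturates,
#' proportional to cathode voltage (67 W at 125 kV by default).
#'
#' @inheritParams klystron_max_power
#' @return Saturation drive power, W.
#' @export
klystron_saturation_drive <- function(voltage, params = klystron_params()) {
  .check_kly_voltage(voltage, params)
  params$pc_per_kv * voltage
}

#' Klystron output power
#'
#' Two-cavity bunching model: the output follows a first-order Bessel
#' function of the bunching parameter, rising linearly at small drive,
#' saturating at the critical drive level, then dropping off as electron
#' bunches dephase. The drive domain is restricted to the first
#' rise-and-fall lobe (drive at most four times the saturation level).
#'
#' @param rf_drive RF drive power, W (vectorized, non-negative).
#' @param voltage Cathode voltage, kV.
#' @param params A [klystron_params()].
#' @return Output power, MW.
#' @export
klystron_output <- function(rf_drive, voltage, params = klystron_params()) {
  if (any(rf_drive < 0)) stop("RF drive power must be non-negative")
  pmax <- klystron_max_power(voltage, params)
  pc <- klystron_saturation_drive(voltage, params)
  if (any(rf_drive > 4 * pc))
    stop(sprintf(
      "RF drive %g W beyond modelled drive range (max %g W at %g kV)",
      max(rf_drive), 4 * min(pc), voltage[1L]))
  x <- 1.84 * sqrt(rf_drive / pc)
  out <- ifelse(rf_drive == 0, 0,
                10 * pmax * (besselJ(x, 1) / x)^2 * (rf_drive / pc))
  out
}
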