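## Orchestrator: control-settings registry, 6/15 MV presets, validation and
## the end-to-end simulation.

.linacsim_env <- new.env(parent = emptyenv())

#' Physics parameter bundle
#'
#' Collects the per-subsystem parameter objects used by the end-to-end
#' simulation; each can be overridden (e.g. from a config file).
#'
#' @param klystron A [klystron_params()].
#' @param gun A [gun_params()].
#' @param accelerator An [accelerator_params()].
#' @param bend A [bend_params()].
#' @param steering A [steering_params()].
#' @param target A [target_material()].
#' @param spot_sigma Electron spot RMS size at the target, cm.
#' @param k3 Bremsstrahlung emission-angle shape factor.
#' @return An object of class `linac_params`.
#' @export
linac_params <- function(klystron = klystron_params(), gun = gun_params(),
                         accelerator = accelerator_params(),
                         bend = bend_params(), steering = steering_params(),
                         target = target_material(), spot_sigma = 0.1,
                         k3 = 1) {
  structure(list(klystron = klystron, gun = gun, accelerator = accelerator,
                 bend = bend, steering = steering, target = target,
                 spot_sigma = spot_sigma, k3 = k3),
            class = "linac_params")
}

#' Simulation discretization options
#'
#' Defaults follow the package's reference discretization: 200 depth slabs,
#' 100 log-spaced photon-energy nodes, 101 radial angle nodes over 0.5 rad
#' and a 0.2 cm dose grid over +/-15 cm. Coarser values trade accuracy for
#' speed (relative metrics such as flatness converge quickly).
#'
#' @param n_slabs,n_K,n_angle Spectrum discretization (see
#'   [fluence_spectrum()]).
#' @param grid_spacing,grid_halfwidth Dose-grid spacing and half-extent, cm.
#' @param theta_max,k_min Angle (rad) and photon-energy (MeV) grid floors.
#' @return An object of class `sim_options`.
#' @export
sim_options <- function(n_slabs = 200L, n_K = 100L, n_angle = 101L,
                        grid_spacing = 0.2, grid_halfwidth = 15,
                        theta_max = 0.5, k_min = 0.05) {
  structure(list(n_slabs = as.integer(n_slabs), n_K = as.integer(n_K),
                 n_angle = as.integer(n_angle), grid_spacing = grid_spacing,
                 grid_halfwidth = grid_halfwidth, theta_max = theta_max,
                 k_min = k_min),
            class = "sim_options")
}

#' Control-settings registry
#'
#' The user-adjustable machine parameters, their units and allowed ranges.
#'
#' @return A data frame with columns `field`, `unit`, `min`, `max`.
#' @export
settings_registry <- function() {
  data.frame(
    field = c("rf_drive", "kly_voltage", "gun_voltage", "grid_voltage",
              "bmag_current", "pos_r", "pos_t", "ang_r", "ang_t",
              "jaw_r", "jaw_t", "prf", "pulse_width", "depth",
              "filter_energy"),
    unit = c("W", "kV", "kV", "V", "A", "mA", "mA", "mA", "mA",
             "cm", "cm", "Hz", "us", "cm", "MeV"),
    min = c(0, 100, 0, 0, 0, -500, -500, -500, -500, 0, 0, 0, 0, 1.5, 1),
    max = c(300, 145, 30, 200, 250, 500, 500, 500, 500, 40, 40, 400, 10,
            40, 25),
    stringsAsFactors = FALSE)
}

#' Construct machine control settings
#'
#' All fields carry the units of the service-mode registry
#' ([settings_registry()]). `filter_energy` selects the flattening filter by
#' its design energy (MeV); filters are designed on demand and cached.
#'
#' @param rf_drive RF drive power to the klystron, W.
#' @param kly_voltage Klystron cathode pulse voltage, kV.
#' @param gun_voltage Gun cathode voltage, kV.
#' @param grid_voltage Gun grid bias, V.
#' @param bmag_current Bend-magnet coil current, A.
#' @param pos_r,pos_t,ang_r,ang_t Steering-coil currents, mA.
#' @param jaw_r,jaw_t Full jaw openings at isocenter, cm.
#' @param prf Pulse repetition frequency, Hz.
#' @param pulse_width Pulse width, us.
#' @param depth Water-phantom analysis depth, cm.
#' @param filter_energy Flattening-filter design energy, MeV.
#' @return An object of class `control_settings`.
#' @export
control_settings <- function(rf_drive = 67, kly_voltage = 125,
                             gun_voltage = 12.25, grid_voltage = 0,
                             bmag_current = 150, pos_r = 0, pos_t = 0,
                             ang_r = 0, ang_t = 0, jaw_r = 20, jaw_t = 20,
                             prf = 180, pulse_width = 5, depth = 1.5,
                             filter_energy = 15) {
  s <- list(rf_drive = rf_drive, kly_voltage = kly_voltage,
            gun_voltage = gun_voltage, grid_voltage = grid_voltage,
            bmag_current = bmag_current, pos_r = pos_r, pos_t = pos_t,
            ang_r = ang_r, ang_t = ang_t, jaw_r = jaw_r, jaw_t = jaw_t,
            prf = prf, pulse_width = pulse_width, depth = depth,
            filter_energy = filter_energy)
  structure(s, class = "control_settings")
}

#' Validate control settings against the registry
#'
#' @param settings A [control_settings()].
#' @return A data frame of violations (zero rows when valid) with columns
#'   `field`, `value`, `min`, `max`, `unit`.
#' @export
validate_settings <- function(settings) {
  reg <- settings_registry()
  v <- vapply(reg$field, function(f) as.numeric(settings[[f]]), numeric(1L))
  bad <- !is.finite(v) | v < reg$min | v > reg$max
  data.frame(field = reg$field[bad], value = v[bad], min = reg$min[bad],
             max = reg$max[bad], unit = reg$unit[bad],
             stringsAsFactors = FALSE, row.names = NULL)
}

.stop_on_violations <- function(settings) {
  viol <- validate_settings(settings)
  if (nrow(viol))
    stop("invalid control settings: ",
         paste(sprintf("%s = %g %s outside [%g, %g]", viol$field, viol$value,
                       viol$unit, viol$min, viol$max), collapse = "; "))
}

#' Load a built-in preset
#'
#' The 15 MV preset runs the klystron at its saturated operating point
#' (125 kV, 67 W drive, 9 MW output), with the gun set so beam loading
#' brings the loaded energy to exactly 15 MeV (240 mA at 12.25 kV) and the
#' bend coil matched to that energy. The 6 MV preset keeps the same klystron
#' voltage and gun current but runs the RF drive well below saturation so
#' the loaded energy is exactly 6 MeV, with its own matched coil and a
#' filter flattened for 6 MeV.
#'
#' @param name `"6MV"` or `"15MV"`.
#' @param params A [linac_params()] (presets are derived from its
#'   calibration anchors).
#' @return A [control_settings()].
#' @export
load_preset <- function(name, params = linac_params()) {
  if (!is.character(name) || length(name) != 1L || !name %in% c("6MV", "15MV"))
    stop("unknown preset ", if (is.character(name)) sQuote(name[1L]) else "",
         "; available presets: \"6MV\", \"15MV\"")
  energy <- if (name == "15MV") 15 else 6
  kv <- 125
  i_gun <- 240  # mA; shared nominal gun current for both presets
  gun_v <- (i_gun / params$gun$perveance_eff)^(2 / 3)
  if (name == "15MV") {
    rf <- 67
  } else {
    # run below saturation: solve the drive giving the required guide power
    p_needed <- ((energy + (i_gun / 1000) * params$accelerator$shunt_impedance / 2)^2 /
                   params$accelerator$shunt_impedance)
    rf <- stats::uniroot(function(p) klystron_output(p, kv, params$klystron) - p_needed,
                         c(1e-3, klystron_saturation_drive(kv, params$klystron)),
                         tol = 1e-10)$root
  }
  p_out <- klystron_output(rf, kv, params$klystron)
  i_exact <- gun_current(gun_v, 0, params$gun)
  e_loaded <- loaded_energy(p_out, i_exact, params$accelerator)
  control_settings(rf_drive = rf, kly_voltage = kv, gun_voltage = gun_v,
                   bmag_current = bend_current_for_energy(e_loaded, params$bend),
                   filter_energy = energy)
}

.filter_key <- function(energy, geometry, options) {
  paste(format(c(energy, geometry$d_filter, geometry$d_sad, geometry$jaw_r,
                 geometry$jaw_t, options$n_K, options$n_angle,
                 options$n_slabs, options$k_min), digits = 12),
        collapse = "|")
}

.get_filter <- function(energy, geometry, options, params) {
  key <- .filter_key(energy, geometry, options)
  if (is.null(.linacsim_env$filters)) .linacsim_env$filters <- list()
  f <- .linacsim_env$filters[[key]]
  if (is.null(f)) {
    f <- design_filter(energy, geometry, target = params$target,
                       n_K = options$n_K, n_angle = options$n_angle,
                       n_slabs = options$n_slabs)
    .linacsim_env$filters[[key]] <- f
  }
  f
}

# Forward chain up to the (unnormalized, per-mA) dose grid and readouts.
.simulate_core <- function(settings, options, params) {
  .stop_on_violations(settings)
  geometry <- beam_geometry(jaw_r = settings$jaw_r, jaw_t = settings$jaw_t)
  p_out <- klystron_output(settings$rf_drive, settings$kly_voltage,
                           params$klystron)
  i_gun <- gun_current(settings$gun_voltage, settings$grid_voltage,
                       params$gun)
  e_acc <- loaded_energy(p_out, i_gun, params$accelerator)
  spec <- beam_spectrum(e_acc, params$accelerator)
  setp <- setpoint_energy(settings$bmag_current, params$bend)
  tr <- transmit(spec, i_gun, setp, params$bend)
  inc <- steer(phase_space(spot_sigma = params$spot_sigma),
               pos_coil_ma = c(settings$pos_r, settings$pos_t),
               ang_coil_ma = c(settings$ang_r, settings$ang_t),
               params = params$steering)
  out <- list(rf_out = p_out, gun_current = i_gun, beam_energy = e_acc,
              setpoint = setp, target_current = tr$target_current,
              transmitted_energy = tr$transmitted_mean_energy,
              incidence = inc, geometry = geometry)
  viable <- tr$target_current > 1e-9 &&
    tr$transmitted_mean_energy > max(0.3, 2 * options$k_min)
  if (!viable) {
    x <- seq(-options$grid_halfwidth, options$grid_halfwidth,
             by = options$grid_spacing)
    out$grid <- structure(list(x = x, y = x,
                               values = matrix(0, length(x), length(x)),
                               depth = settings$depth),
                          class = "dose_grid")
    out$cax_per_ma <- 0
    return(out)
  }
  fs <- fluence_spectrum(tr$transmitted_mean_energy, current = 1,
                         incidence = inc, target = params$target,
                         n_K = options$n_K, n_angle = options$n_angle,
                         n_slabs = options$n_slabs, k3 = params$k3,
                         theta_max = options$theta_max,
                         k_min = options$k_min)
  ps <- project_to_plane(fs, geometry, grid_spacing = options$grid_spacing,
                         grid_halfwidth = options$grid_halfwidth)
  filt <- .get_filter(settings$filter_energy, geometry, options, params)
  ps <- attenuate(ps, filt, geometry)
  ps <- collimate(ps, geometry)
  dm <- kerma_dose(ps, settings$depth)
  grid <- spot_convolve(dm, params$spot_sigma, geometry)
  out$grid <- grid
  out$cax_per_ma <- .axis_dose_at(grid, "r", 0)
  out
}

.cal_key <- function(options, params) {
  paste(format(unlist(options), digits = 12),
        format(unlist(params[c("spot_sigma", "k3")]), digits = 12),
        format(unlist(params$accelerator), digits = 12),
        format(unlist(params$bend), digits = 12),
        format(unlist(params$klystron), digits = 12),
        format(unlist(params$gun), digits = 12),
        collapse = "|")
}

#' Dose calibration for a given discretization
#'
#' Fixes the single absolute-dose scalar so the 15 MV preset reads
#' 420 cGy/min on the central axis at 1.5 cm depth with the reference pulse
#' structure (180 Hz, 5 us). Computed once per discretization/parameter set
#' and cached.
#'
#' @param options A [sim_options()].
#' @param params A [linac_params()].
#' @return A [dose_calibration()].
#' @export
linac_calibration <- function(options = sim_options(),
                              params = linac_params()) {
  key <- .cal_key(options, params)
  if (is.null(.linacsim_env$cal)) .linacsim_env$cal <- list()
  cal <- .linacsim_env$cal[[key]]
  if (is.null(cal)) {
    ref <- .simulate_core(load_preset("15MV", params), options, params)
    anchor <- ref$cax_per_ma * ref$target_current
    if (anchor <= 0) stop("dose calibration failed: reference preset gives zero dose")
    cal <- dose_calibration(scalar = 420 / anchor)
    .linacsim_env$cal[[key]] <- cal
  }
  cal
}

#' Run the full machine simulation
#'
#' Chains klystron output, gun current and beam loading, bend-magnet
#' windowing, steering, thick-target bremsstrahlung, flattening filter and
#' jaws, and the kerma dose model into the service-mode readouts. The
#' computation is deterministic: identical settings give bit-identical
#' results.
#'
#' @param settings A [control_settings()] (must validate).
#' @param options A [sim_options()].
#' @param params A [linac_params()].
#' @return An object of class `linac_result`: readouts `rf_out` (MW),
#'   `gun_current`, `target_current` (mA), `beam_energy`,
#'   `transmitted_energy` (MeV), `dose_rate` (cGy/min), `flatness`,
#'   `symmetry_r`, `symmetry_t` (%), derived readouts `pfn_kv`,
#'   `kly_current_a`, and the calibrated `dose_grid` (cGy/min).
#' @export
simulate_linac <- function(settings, options = sim_options(),
                           params = linac_params()) {
  core <- .simulate_core(settings, options, params)
  cal <- linac_calibration(options, params)
  rate <- dose_rate(core$cax_per_ma, core$target_current, settings$prf,
                    settings$pulse_width, cal)
  grid <- core$grid
  if (core$cax_per_ma > 0)
    grid$values <- grid$values * (rate / (core$cax_per_ma))
  fl <- if (core$cax_per_ma > 0) flatness(grid, settings$jaw_r, "r") else NA_real_
  sr <- if (core$cax_per_ma > 0) symmetry(grid, settings$jaw_r, "r") else NA_real_
  st <- if (core$cax_per_ma > 0) symmetry(grid, settings$jaw_t, "t") else NA_real_
  structure(list(settings = settings,
                 rf_out = core$rf_out,
                 gun_current = core$gun_current,
                 target_current = core$target_current,
                 beam_energy = core$beam_energy,
                 transmitted_energy = core$transmitted_energy,
                 setpoint = core$setpoint,
                 dose_rate = rate,
                 flatness = fl, symmetry_r = sr, symmetry_t = st,
                 pfn_kv = settings$kly_voltage,
                 kly_current_a = core$rf_out * 1e6 /
                   (settings$kly_voltage * 1e3),
                 dose_grid = grid),
            class = "linac_result")
}

#' @export
print.linac_result <- function(x, ...) {
  cat("Linac simulation result\n")
  cat(sprintf("  RF out        %8.3f MW\n", x$rf_out))
  cat(sprintf("  Gun I         %8.2f mA\n", x$gun_current))
  cat(sprintf("  Target I      %8.2f mA\n", x$target_current))
  cat(sprintf("  Beam energy   %8.3f MeV\n", x$beam_energy))
  cat(sprintf("  Dose rate     %8.1f cGy/min\n", x$dose_rate))
  cat(sprintf("  Flatness      %8.3f\n", x$flatness))
  cat(sprintf("  Rad S / Trans S %6.2f %% / %.2f %%\n",
              x$symmetry_r, x$symmetry_t))
  invisible(x)
}

#' Sweep one control parameter
#'
#' Runs one simulation per value with all other fields fixed and collects
#' the main readouts in a tidy table.
#'
#' @param settings Base [control_settings()].
#' @param parameter Name of a settings field.
#' @param values Numeric vector of values to sweep.
#' @param options,params See [simulate_linac()].
#' @return A data frame with one row per value: `value`, `rf_out`,
#'   `gun_current`, `target_current`, `beam_energy`, `dose_rate`,
#'   `flatness`, `symmetry_r`, `symmetry_t`.
#' @export
sweep_parameter <- function(settings, parameter, values,
                            options = sim_options(),
                            params = linac_params()) {
  if (!parameter %in% settings_registry()$field)
    stop("unknown sweep parameter ", sQuote(parameter))
  empty <- data.frame(value = numeric(0), rf_out = numeric(0),
                      gun_current = numeric(0), target_current = numeric(0),
                      beam_energy = numeric(0), dose_rate = numeric(0),
                      flatness = numeric(0), symmetry_r = numeric(0),
                      symmetry_t = numeric(0))
  if (!length(values)) return(empty)
  rows <- lapply(values, function(v) {
    s <- settings
    s[[parameter]] <- v
    r <- simulate_linac(s, options, params)
    data.frame(value = v, rf_out = r$rf_out, gun_current = r$gun_current,
               target_current = r$target_current,
               beam_energy = r$beam_energy, dose_rate = r$dose_rate,
               flatness = r$flatness, symmetry_r = r$symmetry_r,
               symmetry_t = r$symmetry_t)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Find the bend coil current maximizing target current
#'
#' Reproduces the bend-matching step of beam tuning: with all other settings
#' fixed, scans the coil current on a uniform grid around the load-line
#' estimate and returns the value maximizing the transmitted (target)
#' current.
#'
#' @param settings A [control_settings()].
#' @param step Scan grid step, A.
#' @param span Half-width of the scan window around the estimate, A.
#' @param params A [linac_params()].
#' @return A list: `current` (A), `target_current` (mA) at the optimum.
#' @export
match_bend_current <- function(settings, step = 0.01, span = 5,
                               params = linac_params()) {
  p_out <- klystron_output(settings$rf_drive, settings$kly_voltage,
                           params$klystron)
  i_gun <- gun_current(settings$gun_voltage, settings$grid_voltage,
                       params$gun)
  e_acc <- loaded_energy(p_out, i_gun, params$accelerator)
  spec <- beam_spectrum(e_acc, params$accelerator)
  i0 <- bend_current_for_energy(e_acc, params$bend)
  grid <- seq(max(0, i0 - span), i0 + span, by = step)
  tr <- transmit(spec, i_gun, setpoint_energy(grid, params$bend),
                 params$bend)
  best <- which.max(tr$target_current)
  list(current = grid[best], target_current = tr$target_current[best])
}

#' Settings reaching a requested beam energy
#'
#' Keeps the base klystron operating point and solves the gun voltage so
#' beam loading brings the loaded energy exactly to `energy`, then matches
#' the bend coil. The flattening filter of the base settings is kept, which
#' makes this the natural tool for studying a fixed filter across energies.
#'
#' @param energy Desired loaded beam energy, MeV.
#' @param base Base [control_settings()] (default: the 15 MV preset).
#' @param params A [linac_params()].
#' @return A [control_settings()].
#' @export
settings_for_energy <- function(energy, base = load_preset("15MV"),
                                params = linac_params()) {
  stopifnot(energy > 0)
  p_out <- klystron_output(base$rf_drive, base$kly_voltage, params$klystron)
  z <- params$accelerator$shunt_impedance
  v0 <- sqrt(p_out * z)  # no-load energy, MV
  if (energy >= v0)
    stop(sprintf("energy %g MeV unreachable: no-load energy is %.2f MeV",
                 energy, v0))
  i_needed <- 2 * (v0 - energy) / z * 1000  # mA
  gun_v <- (i_needed / params$gun$perveance_eff)^(2 / 3)
  s <- base
  s$gun_voltage <- gun_v
  s$bmag_current <- bend_current_for_energy(energy, params$bend)
  s
}
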