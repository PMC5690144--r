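## Bundled physics coefficient tables and their interpolation.

.materials_env <- new.env(parent = emptyenv())

#' Construct a material coefficient table
#'
#' A `material_table` holds an energy-dependent coefficient (electron mass
#' stopping power, photon mass attenuation, or mass energy-absorption) on a
#' strictly increasing energy grid. Queries between nodes use log-log
#' interpolation, the standard choice for near-power-law attenuation data.
#'
#' @param energy Numeric vector of photon/electron energies in MeV, strictly
#'   increasing.
#' @param value Positive coefficient values (MeV cm^2/g or cm^2/g).
#' @param quantity One of `"stopping_power"`, `"attenuation"`,
#'   `"energy_absorption"`.
#' @param material Material name, used in error messages.
#' @return An object of class `material_table`.
#' @export
material_table <- function(energy, value,
                           quantity = c("stopping_power", "attenuation",
                                        "energy_absorption"),
                           material = "unknown") {
  quantity <- match.arg(quantity)
  energy <- as.numeric(energy)
  value <- as.numeric(value)
  if (length(energy) != length(value) || length(energy) < 2L)
    stop("material table needs matching energy/value vectors of length >= 2")
  if (any(diff(energy) <= 0))
    stop("material table energy grid must be strictly increasing")
  if (any(value <= 0) || any(!is.finite(value)))
    stop("material table values must be positive and finite")
  structure(list(energy = energy, value = value,
                 quantity = quantity, material = material),
            class = "material_table")
}

#' Read a material table from a plain-text fixture
#'
#' Fixtures are two-column text files (`energy_MeV value`) with `#` comment
#' lines and a header row naming the columns.
#'
#' @param path Path to the fixture file.
#' @return A [material_table()].
#' @export
read_material_table <- function(path) {
  hdr <- readLines(path, n = 10L)
  grab <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (length(ln)) trimws(sub(paste0("^# ", key, ":"), "", ln[1L])) else "unknown"
  }
  dat <- utils::read.table(path, comment.char = "#", header = TRUE)
  material_table(dat[[1L]], dat[[2L]], quantity = grab("quantity"),
                 material = grab("material"))
}

#' Interpolate a material table
#'
#' Log-log interpolation between bracketing grid nodes; exact at nodes.
#' Energies outside the tabulated range raise an error naming the table.
#'
#' @param table A [material_table()].
#' @param energy Query energies, MeV (vectorized).
#' @return Interpolated coefficient values.
#' @export
mat_interp <- function(table, energy) {
  stopifnot(inherits(table, "material_table"))
  rng <- range(table$energy)
  bad <- !is.finite(energy) | energy < rng[1L] | energy > rng[2L]
  if (any(bad))
    stop(sprintf(
      "energy %g MeV outside the %s %s table range [%g, %g] MeV",
      energy[bad][1L], table$material, table$quantity, rng[1L], rng[2L]))
  exp(stats::approx(log(table$energy), log(table$value), log(energy))$y)
}

.load_table <- function(name) {
  if (is.null(.materials_env[[name]])) {
    path <- system.file("extdata", paste0(name, ".txt"), package = "linacsim",
                        mustWork = TRUE)
    .materials_env[[name]] <- read_material_table(path)
  }
  .materials_env[[name]]
}

#' Bundled coefficient accessors
#'
#' Convenience accessors for the bundled tables: total (collision plus
#' radiative) mass stopping power of tungsten, photon mass attenuation of
#' tungsten, water and copper, and the mass energy-absorption coefficient of
#' water. All are vectorized over energy and valid on 0.01-30 MeV.
#'
#' @param E,K Electron (`E`) or photon (`K`) energy in MeV.
#' @return Coefficient values in MeV cm^2/g (`tungsten_stopping_power`) or
#'   cm^2/g (the rest).
#' @name material-accessors
NULL

#' @rdname material-accessors
#' @export
tungsten_stopping_power <- function(E) mat_interp(.load_table("tungsten_stopping_power"), E)

#' @rdname material-accessors
#' @export
tungsten_mu <- function(K) mat_interp(.load_table("tungsten_attenuation"), K)

#' @rdname material-accessors
#' @export
water_mu <- function(K) mat_interp(.load_table("water_attenuation"), K)

#' @rdname material-accessors
#' @export
water_mu_ab <- function(K) mat_interp(.load_table("water_energy_absorption"), K)

#' @rdname material-accessors
#' @export
copper_mu <- function(K) mat_interp(.load_table("copper_attenuation"), K)

#' Bremsstrahlung target material
#'
#' Defaults describe a tungsten conversion target typical of medical linacs:
#' Z = 74, A = 183.84 g/mol, density 19.3 g/cm^3, radiation length
#' 6.76 g/cm^2, thickness 0.10 cm.
#'
#' @param Z Atomic number (integer).
#' @param A Atomic mass, g/mol.
#' @param density g/cm^3.
#' @param X0 Radiation length, g/cm^2.
#' @param thickness Target thickness, cm.
#' @return An object of class `target_material`.
#' @export
target_material <- function(Z = 74L, A = 183.84, density = 19.3,
                            X0 = 6.76, thickness = 0.10) {
  stopifnot(Z > 0, Z == round(Z), A > 0, density > 0, X0 > 0, thickness >= 0)
  structure(list(Z = as.integer(Z), A = A, density = density,
                 X0 = X0, thickness = thickness),
            class = "target_material")
}
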