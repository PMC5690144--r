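## Thick-target bremsstrahlung: electron slowing, angular widths, photon
## yield and the depth-integrated energy-fluence spectrum.

.SIGMA_E_CAP <- 0.8  # rad; beyond this the electrons are fully dispersed

#' Mean electron energy vs depth in the target
#'
#' Integrates `dE/dx = -S(E) rho` through the target with midpoint
#' (second-order) steps on `n_slabs` equal slabs. Energies are clamped at
#' zero once the beam ranges out; downstream slabs are marked depleted.
#'
#' @param E0 Incident kinetic energy, MeV (within the stopping-power table).
#' @param target A [target_material()].
#' @param n_slabs Number of depth slabs; at least 100 is recommended for
#'   converged profiles (very small counts are allowed for hand-checkable
#'   decompositions).
#' @return A list of class `depth_profile`: `depth` (slab midpoints, cm),
#'   `energy` (mean kinetic energy per slab, MeV, 0 when depleted), `dx`
#'   (slab width, cm), `exit_energy` (MeV).
#' @export
electron_energy_profile <- function(E0, target = target_material(),
                                    n_slabs = 200L) {
  stopifnot(E0 > 0, n_slabs >= 1L)
  emin <- 0.011  # just above the table floor; below this the slab is depleted
  if (E0 < emin) stop("incident energy below the stopping-power table range")
  tungsten_stopping_power(E0)  # range check up front (errors if E0 > 30 MeV)
  dx <- target$thickness / n_slabs
  rho <- target$density
  e_here <- E0
  e_mid <- numeric(n_slabs)
  for (i in seq_len(n_slabs)) {
    if (e_here < emin) {
      e_mid[i] <- 0
      e_here <- 0
      next
    }
    k1 <- tungsten_stopping_power(e_here) * rho
    e_half <- e_here - k1 * dx / 2
    k2 <- if (e_half >= emin) tungsten_stopping_power(e_half) * rho else k1
    e_next <- max(0, e_here - k2 * dx)
    e_mid[i] <- (e_here + e_next) / 2
    if (e_mid[i] < emin) e_mid[i] <- 0
    e_here <- e_next
  }
  structure(list(depth = (seq_len(n_slabs) - 0.5) * dx, energy = e_mid,
                 dx = dx, exit_energy = e_here),
            class = "depth_profile")
}

#' Multiple-scattering RMS angle at depth
#'
#' Highland form of Moliere theory, evaluated with the incident kinetic
#' energy: `13.6 MeV / (E0 + me c^2) * sqrt(x/X0) * (1 + 0.038 ln(x/X0))`
#' (depth `x` in g/cm^2). The logarithmic bracket is clamped at zero and the
#' result saturates at 0.8 rad, where the electrons are completely dispersed
#' in the target.
#'
#' @param depth Depth in the target, cm (non-negative, vectorized).
#' @param E0 Incident kinetic energy, MeV.
#' @param target A [target_material()].
#' @return RMS scattering angle, rad, in `[0, 0.8]`.
#' @export
scatter_sigma <- function(depth, E0, target = target_material()) {
  stopifnot(all(depth >= 0), E0 >= 0)
  xr <- depth * target$density / target$X0
  raw <- ifelse(xr > 0,
                13.6 / (E0 + .ME_C2) * sqrt(xr) *
                  pmax(0, 1 + 0.038 * log(xr)),
                0)
  pmin(.SIGMA_E_CAP, raw)
}

#' Bremsstrahlung intrinsic emission RMS angle
#'
#' Characteristic emission angle `k3 * me c^2 / (E + me c^2)`, shrinking as
#' the local electron energy grows.
#'
#' @param mean_energy Local mean electron kinetic energy, MeV (vectorized).
#' @param k3 Dimensionless shape factor (default 1).
#' @return RMS emission angle, rad.
#' @export
brems_sigma <- function(mean_energy, k3 = 1) {
  stopifnot(all(mean_energy >= 0), k3 > 0)
  k3 * .ME_C2 / (mean_energy + .ME_C2)
}

#' Relative thick-target bremsstrahlung yield
#'
#' Linear-in-K fit to tabulated scaled bremsstrahlung spectra:
#' `K dsigma/dK = (NA/A) Z^2 a (1 - b K / E)`, with a = 11 mb and b = 0.83,
#' zero for photon energies above the local electron energy.
#'
#' @param K Photon energy, MeV (vectorized).
#' @param E_local Local mean electron kinetic energy, MeV.
#' @param target A [target_material()].
#' @param a_mb Intercept cross-section parameter, millibarn.
#' @param b Slope parameter (dimensionless).
#' @return Relative yield (energy-weighted cross section per unit mass,
#'   arbitrary-but-consistent units).
#' @export
brems_yield <- function(K, E_local, target = target_material(),
                        a_mb = 11, b = 0.83) {
  stopifnot(all(K > 0))
  if (E_local <= 0) return(numeric(length(K)) * 0)
  const <- 6.02214076e23 / target$A * target$Z^2 * a_mb * 1e-27  # cm^2/g
  ifelse(K <= E_local, const * (1 - b * K / E_local), 0)
}

#' Depth-integrated photon energy-fluence spectrum off the target
#'
#' For each depth slab: local yield, attenuated through the remaining target
#' thickness, spread over a radially symmetric Gaussian angular kernel whose
#' variance parameter is `sigma_e^2 + sigma_b^2` (multiple scattering plus
#' intrinsic emission). Contributions are summed over slabs; depleted slabs
#' contribute nothing. The kernel is normalized so its integral over the
#' small-angle plane is 1 for every slab, and the overall scale is linear in
#' the target current. The angle grid is radial about the beam's incidence
#' direction; the incidence centroid is carried alongside and applied when
#' the spectrum is projected to a spatial plane.
#'
#' @param energy Incident mean electron kinetic energy, MeV.
#' @param current Time-averaged target current, mA.
#' @param incidence A [phase_space()] at the target.
#' @param target A [target_material()].
#' @param n_K,n_angle,n_slabs Discretization: log-spaced photon-energy nodes
#'   on `[k_min, energy]`, radial angle nodes on `[0, theta_max]`, and depth
#'   slabs.
#' @param k3 Shape factor for [brems_sigma()].
#' @param theta_max Largest tabulated radial angle, rad.
#' @param k_min Lowest tabulated photon energy, MeV.
#' @return An object of class `fluence_spectrum`: `K` (MeV), `theta` (rad,
#'   radial), `values` (matrix `n_K x n_angle`, energy fluence per unit K),
#'   plus `energy`, `current` and `incidence`.
#' @export
fluence_spectrum <- function(energy, current = 1, incidence = phase_space(),
                             target = target_material(),
                             n_K = 100L, n_angle = 101L, n_slabs = 200L,
                             k3 = 1, theta_max = 0.5, k_min = 0.05) {
  stopifnot(current >= 0, energy > k_min * 1.05,
            n_K >= 10L, n_angle >= 11L)
  K <- exp(seq(log(k_min), log(energy), length.out = n_K))
  theta <- seq(0, theta_max, length.out = n_angle)
  vals <- matrix(0, n_K, n_angle)
  if (target$thickness > 0 && current > 0) {
    prof <- electron_energy_profile(energy, target, n_slabs)
    live <- prof$energy > 0
    if (any(live)) {
      x <- prof$depth[live]
      e_loc <- prof$energy[live]
      rho <- target$density
      mu_w <- tungsten_mu(K)
      # n_K x n_live: yield and self-attenuation through the remaining target
      atten <- exp(-outer(mu_w * rho, target$thickness - x))
      yld <- vapply(e_loc, function(e) brems_yield(K, e, target),
                    numeric(n_K))
      s2 <- scatter_sigma(x, energy, target)^2 + brems_sigma(e_loc, k3)^2
      # n_live x n_angle: unit-normalized 2-D angular kernel per slab
      kern <- exp(-outer(1 / s2, theta^2)) / (pi * s2)
      vals <- (yld * atten) %*% (kern * rho * prof$dx)
    }
  }
  structure(list(K = K, theta = theta, values = current * vals,
                 energy = energy, current = current, incidence = incidence),
            class = "fluence_spectrum")
}
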