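## Flattening filter, jaw collimation and the angular-to-spatial projection.

.RHO_CU <- 8.96  # g/cm^3, flattening-filter copper

#' Treatment-head geometry
#'
#' @param d_filter Source-to-filter distance, cm.
#' @param d_sad Source-to-isocenter distance, cm (must exceed `d_filter`).
#' @param jaw_r,jaw_t Full jaw openings at the isocenter plane, in-plane and
#'   cross-plane, cm.
#' @return An object of class `beam_geometry`.
#' @export
beam_geometry <- function(d_filter = 12.5, d_sad = 100,
                          jaw_r = 20, jaw_t = 20) {
  stopifnot(d_filter > 0, d_sad > d_filter, jaw_r >= 0, jaw_t >= 0)
  structure(list(d_filter = d_filter, d_sad = d_sad,
                 jaw_r = jaw_r, jaw_t = jaw_t),
            class = "beam_geometry")
}

#' Project an angular fluence spectrum onto the isocenter plane
#'
#' Small-angle ray projection: a photon leaving the spot at transverse
#' position `r0` with angle `th` lands at `r0 + d_sad * th` in the isocenter
#' plane, so the radially tabulated angular spectrum becomes a spatial
#' distribution centred at the spot position plus `d_sad` times the beam
#' tilt.
#'
#' @param fs A [fluence_spectrum()] (angular frame).
#' @param geometry A [beam_geometry()].
#' @param grid_spacing,grid_halfwidth Spatial grid: uniform spacing (cm) over
#'   `[-grid_halfwidth, grid_halfwidth]` in both axes.
#' @return An object of class `plane_spectrum`: `K` (MeV), `x`, `y` (cm),
#'   `values` (array `n_K x n_x x n_y`), `center` (cm).
#' @export
project_to_plane <- function(fs, geometry = beam_geometry(),
                             grid_spacing = 0.2, grid_halfwidth = 15) {
  stopifnot(inherits(fs, "fluence_spectrum"))
  x <- seq(-grid_halfwidth, grid_halfwidth, by = grid_spacing)
  y <- x
  inc <- fs$incidence
  center <- inc$position + geometry$d_sad * inc$angle / 1000  # mrad -> rad
  u <- sqrt(outer((x - center[1L])^2, (y - center[2L])^2, "+")) /
    geometry$d_sad
  nK <- length(fs$K)
  vals <- array(0, dim = c(nK, length(x), length(y)))
  for (k in seq_len(nK)) {
    v <- stats::approx(fs$theta, fs$values[k, ], u, rule = 1)$y
    v[is.na(v)] <- 0
    vals[k, , ] <- v
  }
  structure(list(K = fs$K, x = x, y = y, values = vals, center = center),
            class = "plane_spectrum")
}

#' Design a flattening filter for a given beam energy
#'
#' Numerically inverts the unflattened profile: the open-beam dose profile at
#' the design depth is computed for the design energy, and the conical filter
#' thickness is iteratively adjusted (using the copper attenuation
#' coefficient at the local fluence-weighted mean photon energy) until the
#' filtered profile is uniform across the flattened region, which extends to
#' 90% of the jaw half-opening. The thickness is forced non-increasing with
#' radius. Deterministic: identical inputs give an identical profile.
#'
#' @param design_energy Incident electron energy the filter flattens, MeV.
#' @param geometry A [beam_geometry()].
#' @param target A [target_material()].
#' @param tolerance Relative flatness tolerance of the design (default 2%).
#' @param depth Design depth in water, cm.
#' @param n_K,n_angle,n_slabs Spectrum discretization, as in
#'   [fluence_spectrum()].
#' @param max_iter Iteration cap; non-convergence raises an error.
#' @return An object of class `filter_profile`: `radius` (cm, filter plane),
#'   `thickness` (cm, non-increasing), `material`, `density`,
#'   `design_energy`.
#' @export
design_filter <- function(design_energy, geometry = beam_geometry(),
                          target = target_material(), tolerance = 0.02,
                          depth = 1.5, n_K = 100L, n_angle = 101L,
                          n_slabs = 200L, max_iter = 60L) {
  fs <- fluence_spectrum(design_energy, current = 1,
                         incidence = phase_space(), target = target,
                         n_K = n_K, n_angle = n_angle, n_slabs = n_slabs)
  r_flat <- 0.9 * max(geometry$jaw_r, geometry$jaw_t) / 2
  r_iso <- seq(0, r_flat, length.out = 91L)
  u <- r_iso / geometry$d_sad
  psi <- vapply(seq_along(fs$K),
                function(k) stats::approx(fs$theta, fs$values[k, ], u)$y,
                numeric(length(u)))          # n_r x n_K
  psi <- t(psi)                              # n_K x n_r
  w <- water_mu_ab(fs$K) * exp(-water_mu(fs$K) * depth)
  tk <- .trapz_weights(fs$K)
  thick <- numeric(length(r_iso))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    att <- exp(-outer(copper_mu(fs$K) * .RHO_CU, thick))
    pa <- psi * att
    d_r <- colSums((w * tk) * pa)
    ratio <- d_r / d_r[length(d_r)]
    if (max(abs(ratio - 1)) <= tolerance / 2) {
      converged <- TRUE
      break
    }
    ebar <- colSums((fs$K * tk) * pa) / colSums(tk * pa)
    thick <- thick + log(ratio) / (copper_mu(ebar) * .RHO_CU)
    thick <- pmax(0, thick)
    thick <- rev(cummax(rev(thick)))  # conical: non-increasing outward
  }
  if (!converged)
    stop("flattening-filter design did not converge; relax the tolerance")
  r_filter <- r_iso * geometry$d_filter / geometry$d_sad
  # open (zero-thickness) skirt beyond the flattened region
  r_filter <- c(r_filter, max(r_filter) * 1.5)
  thick <- c(thick, 0)
  structure(list(radius = r_filter, thickness = thick, material = "copper",
                 density = .RHO_CU, design_energy = design_energy),
            class = "filter_profile")
}

#' Attenuate a plane spectrum through the flattening filter
#'
#' Each isocenter-plane position is mapped back to the filter plane along the
#' ray from the source (`r_filter = r_iso * d_filter / d_sad`) and every
#' energy is attenuated by `exp(-mu(K) rho t(r))`.
#'
#' @param ps A `plane_spectrum` from [project_to_plane()].
#' @param filter A [design_filter()] profile.
#' @param geometry A [beam_geometry()].
#' @return The attenuated `plane_spectrum`.
#' @export
attenuate <- function(ps, filter, geometry = beam_geometry()) {
  stopifnot(inherits(ps, "plane_spectrum"), inherits(filter, "filter_profile"))
  rf <- sqrt(outer(ps$x^2, ps$y^2, "+")) * geometry$d_filter / geometry$d_sad
  tmap <- stats::approx(filter$radius, filter$thickness, rf, rule = 2)$y
  tmap <- matrix(tmap, length(ps$x), length(ps$y))
  mu <- copper_mu(ps$K) * filter$density
  for (k in seq_along(ps$K))
    ps$values[k, , ] <- ps$values[k, , ] * exp(-mu[k] * tmap)
  ps
}

#' Collimate a plane spectrum with the jaws
#'
#' Jaws are ideal absorbers: values are zeroed outside the rectangular
#' aperture, taken half-open (`[-J/2, +J/2)`) at the isocenter plane.
#'
#' @param ps A `plane_spectrum`.
#' @param geometry A [beam_geometry()] supplying the jaw openings.
#' @return The collimated `plane_spectrum`. Idempotent.
#' @export
collimate <- function(ps, geometry = beam_geometry()) {
  stopifnot(inherits(ps, "plane_spectrum"))
  mx <- ps$x >= -geometry$jaw_r / 2 & ps$x < geometry$jaw_r / 2
  my <- ps$y >= -geometry$jaw_t / 2 & ps$y < geometry$jaw_t / 2
  mask <- outer(mx, my)
  for (k in seq_along(ps$K))
    ps$values[k, , ] <- ps$values[k, , ] * mask
  ps
}

# composite trapezoid weights for an (irregular) grid
.trapz_weights <- function(g) {
  n <- length(g)
  w <- numeric(n)
  d <- diff(g)
  w[1L] <- d[1L] / 2
  w[n] <- d[n - 1L] / 2
  if (n > 2L) w[2L:(n - 1L)] <- (d[-(n - 1L)] + d[-1L]) / 2
  w
}
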