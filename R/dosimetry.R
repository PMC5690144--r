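## Kerma-based dose at depth, finite-spot convolution and beam metrics.

#' Kerma-approximation dose map at depth
#'
#' Beyond the build-up depth the dose rate equals the collision kerma:
#' per-position quadrature over photon energy of the fluence, attenuated
#' through `depth` cm of water, weighted by the water mass energy-absorption
#' coefficient. Shallower depths are outside the model's validity and raise
#' an error unless explicitly overridden (e.g. depth 0 for an in-air map).
#'
#' @param ps A `plane_spectrum` at the isocenter plane.
#' @param depth Depth in water, cm (at least 1.5 unless `allow_buildup`).
#' @param allow_buildup Set `TRUE` to evaluate shallower than 1.5 cm (the
#'   kerma approximation then ignores the missing build-up).
#' @return A list of class `dose_map`: `x`, `y` (cm), `values` (matrix,
#'   unnormalized dose rate), `depth`.
#' @export
kerma_dose <- function(ps, depth, allow_buildup = FALSE) {
  stopifnot(inherits(ps, "plane_spectrum"), depth >= 0)
  if (depth < 1.5 && !allow_buildup)
    stop("depth is inside the build-up region (< 1.5 cm), ",
         "where the kerma approximation does not hold")
  w <- water_mu_ab(ps$K) * exp(-water_mu(ps$K) * depth) * .trapz_weights(ps$K)
  vals <- matrix(0, length(ps$x), length(ps$y))
  for (k in seq_along(ps$K))
    vals <- vals + w[k] * ps$values[k, , ]
  structure(list(x = ps$x, y = ps$y, values = vals, depth = depth),
            class = "dose_map")
}

# 1-D "same" convolution with an odd-length kernel, zero-padded edges
.conv1_same <- function(v, kern) {
  h <- (length(kern) - 1L) / 2L
  full <- stats::convolve(c(numeric(h), v, numeric(h)), rev(kern),
                          type = "open")
  full[(2L * h + 1L):(2L * h + length(v))]
}

#' Convolve a dose map with the magnified focal spot
#'
#' The finite electron spot blurs the dose distribution with a Gaussian
#' whose width is the spot sigma magnified by `(d_sad - d_filter)/d_filter`
#' (geometric penumbra). The discrete separable kernel is renormalized to
#' sum to one, so the map total is conserved for fields away from the grid
#' edge.
#'
#' @param dm A `dose_map` from [kerma_dose()].
#' @param spot_sigma Electron spot RMS size at the target, cm.
#' @param geometry A [beam_geometry()] supplying the magnification.
#' @return A list of class `dose_grid` with the same fields as the input
#'   map, blurred.
#' @export
spot_convolve <- function(dm, spot_sigma, geometry = beam_geometry()) {
  stopifnot(inherits(dm, "dose_map"), spot_sigma >= 0)
  dx <- dm$x[2L] - dm$x[1L]
  sig <- spot_sigma * (geometry$d_sad - geometry$d_filter) / geometry$d_filter
  vals <- dm$values
  if (sig > 0) {
    if (dx > sig)
      warning("grid spacing exceeds the penumbra kernel sigma; ",
              "the penumbra is under-resolved")
    h <- max(1L, ceiling(4 * sig / dx))
    kern <- stats::dnorm(seq(-h, h) * dx, sd = sig)
    kern <- kern / sum(kern)
    vals <- apply(vals, 2L, .conv1_same, kern = kern)
    vals <- t(apply(vals, 1L, .conv1_same, kern = kern))
  }
  structure(list(x = dm$x, y = dm$y, values = vals, depth = dm$depth),
            class = "dose_grid")
}

# dose along the principal axis ("r" = in-plane, varying x at y = 0)
.axis_profile <- function(grid, axis = c("r", "t")) {
  axis <- match.arg(axis)
  if (axis == "r") {
    j <- which.min(abs(grid$y))
    list(pos = grid$x, dose = grid$values[, j])
  } else {
    i <- which.min(abs(grid$x))
    list(pos = grid$y, dose = grid$values[i, ])
  }
}

.axis_dose_at <- function(grid, axis, pos) {
  pr <- .axis_profile(grid, axis)
  if (any(pos < min(pr$pos) | pos > max(pr$pos)))
    stop("requested off-axis point lies outside the dose grid")
  stats::approx(pr$pos, pr$dose, pos)$y
}

#' Beam flatness
#'
#' Ratio of the dose rate at the 3/4-jaw off-axis point to the central-axis
#' dose rate: the mean of the two on-axis-line values at
#' `+/- (3/4)(jaw/2)` divided by the value at the axis, per axis.
#'
#' @param grid A `dose_grid`.
#' @param jaw Full jaw opening for the requested axis, cm.
#' @param axis `"r"` (in-plane, default) or `"t"` (cross-plane).
#' @return Dimensionless flatness ratio (1 for a uniform profile).
#' @export
flatness <- function(grid, jaw, axis = c("r", "t")) {
  axis <- match.arg(axis)
  x0 <- 0.75 * jaw / 2
  cax <- .axis_dose_at(grid, axis, 0)
  if (cax <= 0) return(NA_real_)
  mean(.axis_dose_at(grid, axis, c(-x0, x0))) / cax
}

#' Beam symmetry
#'
#' Signed relative difference of the mirrored 3/4-jaw points,
#' `S = 200 (D(+x0) - D(-x0)) / (D(+x0) + D(-x0))` percent; zero for a
#' mirror-symmetric profile.
#'
#' @inheritParams flatness
#' @return Symmetry, percent.
#' @export
symmetry <- function(grid, jaw, axis = c("r", "t")) {
  axis <- match.arg(axis)
  x0 <- 0.75 * jaw / 2
  d <- .axis_dose_at(grid, axis, c(x0, -x0))
  if (sum(d) <= 0) return(NA_real_)
  200 * (d[1L] - d[2L]) / (d[1L] + d[2L])
}

#' Dose-rate calibration
#'
#' One scalar, fixed at build time, converts the computed per-mA kerma rate
#' at the reference conditions (15 MV preset, depth 1.5 cm, central axis,
#' PRF 180 Hz, pulse width 5 us) into 420 cGy/min.
#'
#' @param scalar cGy/min per unit (per-mA kerma rate x mA) at reference PRF
#'   and pulse width.
#' @param prf_ref,width_ref Reference pulse structure (Hz, us).
#' @return An object of class `dose_calibration`.
#' @export
dose_calibration <- function(scalar, prf_ref = 180, width_ref = 5) {
  stopifnot(scalar > 0)
  structure(list(scalar = scalar, prf_ref = prf_ref, width_ref = width_ref),
            class = "dose_calibration")
}

#' Absolute dose rate from the unnormalized kerma rate
#'
#' Dose rate scales linearly with the average current delivered to the
#' target, i.e. with target current, pulse repetition frequency and pulse
#' width.
#'
#' @param cax_unnorm Unnormalized central-axis kerma rate computed from a
#'   unit-current (1 mA) fluence spectrum.
#' @param target_current Target current, mA.
#' @param prf Pulse repetition frequency, Hz.
#' @param pulse_width Pulse width, us.
#' @param cal A [dose_calibration()]; an error is raised when missing.
#' @return Dose rate, cGy/min.
#' @export
dose_rate <- function(cax_unnorm, target_current, prf, pulse_width, cal) {
  if (missing(cal) || !inherits(cal, "dose_calibration"))
    stop("dose rate requested without an initialized dose calibration")
  stopifnot(cax_unnorm >= 0, target_current >= 0, prf >= 0, pulse_width >= 0)
  cal$scalar * cax_unnorm * target_current *
    (prf / cal$prf_ref) * (pulse_width / cal$width_ref)
}
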