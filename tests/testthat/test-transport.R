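test_that("coil constant matches the two-point 10 A/MeV condition", {
  p <- function(E) sqrt((E + 0.511)^2 - 0.511^2)
  expect_equal(calibrate_k2(), (p(10) - p(6)) / 40, tolerance = 1e-14)
  expect_equal(calibrate_k2(), 0.10019, tolerance = 1e-4)
  bp <- bend_params()
  # the two calibration points sit exactly 40 A apart
  expect_equal(bend_current_for_energy(10, bp) - bend_current_for_energy(6, bp),
               40, tolerance = 1e-10)
  # relativistic limit: dI/dE -> 1/k2
  expect_equal((bend_current_for_energy(25, bp) -
                  bend_current_for_energy(24.9, bp)) / 0.1,
               1 / bp$k2, tolerance = 1e-3)
})

test_that("set-point energy is monotone and inverts exactly", {
  bp <- bend_params()
  expect_equal(setpoint_energy(0, bp), 0)
  expect_equal(setpoint_energy(64.79, bp), 6.00, tolerance = 1e-3)
  expect_equal(setpoint_energy(104.79, bp), 10.00, tolerance = 1e-3)
  i <- seq(1, 200, by = 1)
  e <- setpoint_energy(i, bp)
  expect_true(all(diff(e) > 0))
  expect_equal(bend_current_for_energy(e, bp), i, tolerance = 1e-10)
  expect_error(setpoint_energy(-1, bp), "non-negative")
})

test_that("acceptance-window transmission matches numerical Gaussian mass and mean", {
  bp <- bend_params(acceptance_halfwidth = 0.015)
  sp <- beam_spectrum(10, accelerator_params(energy_spread_fraction = 0.03))
  tr <- transmit(sp, 100, 10, bp)
  # window is +/- 0.5 sigma here; oracle by numerical quadrature
  frac_num <- stats::integrate(function(e) stats::dnorm(e, sp$mean, sp$sigma),
                               10 * 0.985, 10 * 1.015)$value
  expect_equal(tr$fraction, frac_num, tolerance = 1e-8)
  expect_equal(tr$fraction, stats::pnorm(0.5) - stats::pnorm(-0.5),
               tolerance = 1e-12)
  expect_equal(tr$target_current, 100 * frac_num, tolerance = 1e-6)
  mean_num <- stats::integrate(function(e) e * stats::dnorm(e, sp$mean, sp$sigma),
                               10 * 0.985, 10 * 1.015)$value / frac_num
  expect_equal(tr$transmitted_mean_energy, mean_num, tolerance = 1e-8)
})

test_that("transmission limits: wide window passes all, far set-point nothing", {
  sp <- beam_spectrum(10)
  wide <- transmit(sp, 50, 10, bend_params(acceptance_halfwidth = 0.19))
  expect_gt(wide$fraction, stats::pnorm(6) - stats::pnorm(-6) - 1e-6)
  expect_equal(wide$transmitted_mean_energy, 10, tolerance = 1e-6)
  far <- transmit(sp, 50, 10 + 5 * sp$sigma * 1.2, bend_params())
  expect_lt(far$fraction, 1e-4)
  # linear in input current
  expect_equal(transmit(sp, 80, 10)$target_current,
               2 * transmit(sp, 40, 10)$target_current)
})

test_that("a set-point scan is maximized essentially at the spectrum mean", {
  # the proportional window width pulls the optimum a hair above the mean
  # (relative shift ~ ln((1+w)/(1-w)) / (4 w (mu/sigma)^2) ~ 5e-4)
  sp <- beam_spectrum(10)
  setp <- seq(9, 11, by = 0.002)
  tr <- transmit(sp, 1, setp)
  expect_lt(abs(setp[which.max(tr$fraction)] - 10), 0.01)
})

test_that("steering is affine: position coils move spot and angle, angle coils angle only", {
  st <- steering_params(coil_gain = 0.1, drift_d = 30)
  ps0 <- phase_space()
  expect_equal(steer(ps0, c(0, 0), c(0, 0), st), ps0)
  # 10 mA on the position coil = 1 mrad: 0.030 cm spot shift + 1 mrad tilt
  s1 <- steer(ps0, c(10, 0), c(0, 0), st)
  expect_equal(s1$position, c(0.030, 0))
  expect_equal(s1$angle, c(1, 0))
  # angle coil leaves the spot position unchanged
  s2 <- steer(ps0, c(0, 0), c(10, 0), st)
  expect_equal(s2$position, c(0, 0))
  expect_equal(s2$angle, c(1, 0))
  # superposition
  s12 <- steer(ps0, c(10, -4), c(10, 6), st)
  s1b <- steer(ps0, c(10, -4), c(0, 0), st)
  s2b <- steer(ps0, c(0, 0), c(10, 6), st)
  expect_equal(s12$position, s1b$position + s2b$position)
  expect_equal(s12$angle, s1b$angle + s2b$angle)
})
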