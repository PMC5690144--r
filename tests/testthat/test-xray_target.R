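test_that("electron slowing matches first-order loss in a thin target and converges", {
  thin <- target_material(thickness = 1e-4)
  prof <- electron_energy_profile(6, thin, n_slabs = 10L)
  taylor <- 6 - tungsten_stopping_power(6) * thin$density * thin$thickness
  expect_equal(prof$exit_energy, taylor, tolerance = 1e-3)
  # surface slab energy is the incident energy to first order
  expect_equal(prof$energy[1L], 6, tolerance = 1e-3)
  # grid self-convergence on the full-thickness target
  tt <- target_material()
  e200 <- electron_energy_profile(15, tt, 200L)$exit_energy
  e400 <- electron_energy_profile(15, tt, 400L)$exit_energy
  expect_equal(e200, e400, tolerance = 1e-3)
  # energy is non-increasing with depth
  expect_true(all(diff(electron_energy_profile(15, tt, 200L)$energy) <= 0))
})

test_that("multiple-scattering angle grows from zero and saturates at 0.8 rad", {
  tt <- target_material()
  expect_identical(scatter_sigma(0, 6, tt), 0)
  # one radiation length of tungsten at 6 MeV: raw Highland value is far
  # beyond the cap, so the returned angle is exactly the saturation value
  x0_cm <- tt$X0 / tt$density
  raw <- 13.6 / (6 + 0.511) * sqrt(1) * (1 + 0.038 * log(1))
  expect_gt(raw, 0.8)
  expect_identical(scatter_sigma(x0_cm, 6, tt), 0.8)
  d <- seq(0, x0_cm, length.out = 100)
  expect_true(all(diff(scatter_sigma(d, 6, tt)) >= 0))
  expect_true(all(scatter_sigma(d, 6, tt) <= 0.8))
})

test_that("intrinsic emission angle follows k3 me c^2 / (E + me c^2)", {
  expect_equal(brems_sigma(6, k3 = 1), 0.511 / 6.511, tolerance = 1e-12)
  expect_equal(brems_sigma(0, k3 = 1.3), 1.3)
  expect_lt(brems_sigma(1e5), 1e-4)
})

test_that("bremsstrahlung yield is linear in K with the printed endpoints", {
  tt <- target_material()
  y0 <- brems_yield(1e-9, 6, tt)   # K -> 0 intercept
  expect_equal(brems_yield(6, 6, tt) / y0, 1 - 0.83, tolerance = 1e-6)
  expect_identical(brems_yield(6.5, 6, tt), 0)
  expect_identical(brems_yield(3, 0, tt), 0)
  k <- c(1, 2, 3, 4, 5)
  y <- brems_yield(k, 6, tt)
  expect_equal(diff(y, differences = 2), rep(0, 3), tolerance = 1e-10)
})

test_that("two-slab fluence spectrum matches a hand-composed sum of slab terms", {
  tt <- target_material(thickness = 0.002)
  fs <- fluence_spectrum(6, current = 2, target = tt, n_K = 12L,
                         n_angle = 11L, n_slabs = 2L, k3 = 1)
  prof <- electron_energy_profile(6, tt, 2L)
  expected <- matrix(0, 12L, 11L)
  for (i in 1:2) {
    s2 <- scatter_sigma(prof$depth[i], 6, tt)^2 + brems_sigma(prof$energy[i])^2
    yld <- brems_yield(fs$K, prof$energy[i], tt)
    att <- exp(-tungsten_mu(fs$K) * tt$density * (tt$thickness - prof$depth[i]))
    kern <- exp(-fs$theta^2 / s2) / (pi * s2)
    expected <- expected + outer(yld * att, kern) * tt$density * prof$dx
  }
  expect_equal(fs$values, 2 * expected, tolerance = 1e-10)
})

test_that("fluence spectrum is linear in current, zero for empty targets, forward peaked", {
  fs1 <- fluence_spectrum(10, current = 1, n_K = 30L, n_angle = 21L,
                          n_slabs = 40L)
  fs2 <- fluence_spectrum(10, current = 2, n_K = 30L, n_angle = 21L,
                          n_slabs = 40L)
  expect_equal(fs2$values, 2 * fs1$values, tolerance = 1e-14)
  fs0 <- fluence_spectrum(10, target = target_material(thickness = 0),
                          n_K = 30L, n_angle = 21L, n_slabs = 40L)
  expect_true(all(fs0$values == 0))
  # on-axis value dominates every off-axis value at each photon energy
  expect_true(all(fs1$values[, 1L] >= fs1$values))
  expect_true(all(fs1$values >= 0))
})

test_that("angular spread of the total spectrum shrinks as energy rises", {
  rms_angle <- function(E) {
    fs <- fluence_spectrum(E, n_K = 40L, n_angle = 61L, n_slabs = 80L)
    w <- colSums(fs$values) * fs$theta  # radial weight in the 2-D plane
    sqrt(sum(w * fs$theta^2) / sum(w))
  }
  expect_gt(rms_angle(6), rms_angle(10))
  expect_gt(rms_angle(10), rms_angle(15))
})
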