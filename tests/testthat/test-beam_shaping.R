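fs_cached <- fluence_spectrum(10, n_K = 30L, n_angle = 41L, n_slabs = 60L)

test_that("projection maps angles to isocenter positions along source rays", {
  geom <- beam_geometry()
  ps <- project_to_plane(fs_cached, geom, grid_spacing = 0.5,
                         grid_halfwidth = 10)
  tot <- apply(ps$values, c(2, 3), sum)
  i0 <- which(ps$x == 0)
  # centered beam: symmetric about the axis, maximum on it
  expect_equal(tot, tot[rev(seq_along(ps$x)), rev(seq_along(ps$y))],
               tolerance = 1e-12)
  expect_equal(which.max(tot[, i0]), i0)
  # a 10 mrad tilt lands 1.0 cm off-axis at 100 cm
  fs_tilt <- fs_cached
  fs_tilt$incidence <- phase_space(angle = c(10, 0))
  pst <- project_to_plane(fs_tilt, geom, grid_spacing = 0.5,
                          grid_halfwidth = 10)
  tott <- apply(pst$values, c(2, 3), sum)
  expect_equal(pst$center, c(1.0, 0))
  expect_equal(ps$x[which.max(tott[, i0])], 1.0)
  # a spot offset translates the distribution by itself
  fs_off <- fs_cached
  fs_off$incidence <- phase_space(position = c(0.5, 0))
  pso <- project_to_plane(fs_off, geom, grid_spacing = 0.5,
                          grid_halfwidth = 10)
  expect_equal(pso$center, c(0.5, 0))
  toto <- apply(pso$values, c(2, 3), sum)
  expect_equal(toto[ps$x == 0.5, ], tot[ps$x == 0, ], tolerance = 1e-12)
})

test_that("filter attenuation is exponential, never amplifies, and hardens the beam", {
  geom <- beam_geometry()
  ps <- project_to_plane(fs_cached, geom, grid_spacing = 1, grid_halfwidth = 8)
  # zero-thickness filter is the identity
  f0 <- structure(list(radius = c(0, 5), thickness = c(0, 0),
                       material = "copper", density = 8.96,
                       design_energy = 10), class = "filter_profile")
  expect_equal(attenuate(ps, f0, geom)$values, ps$values)
  # uniform slab with mu rho t = ln 2 halves a single energy everywhere
  k <- 10L
  t_half <- log(2) / (copper_mu(ps$K[k]) * 8.96)
  fh <- structure(list(radius = c(0, 5), thickness = c(t_half, t_half),
                       material = "copper", density = 8.96,
                       design_energy = 10), class = "filter_profile")
  att <- attenuate(ps, fh, geom)
  expect_equal(att$values[k, , ], ps$values[k, , ] / 2, tolerance = 1e-10)
  expect_true(all(att$values <= ps$values + 1e-15))
  # polyenergetic hardening: mean photon energy rises through the slab
  mean_k <- function(p) {
    w <- apply(p$values, 1, sum)
    sum(p$K * w) / sum(w)
  }
  expect_gt(mean_k(att), mean_k(ps))
})

test_that("jaw collimation zeroes outside the half-open aperture and is idempotent", {
  geom <- beam_geometry(jaw_r = 8, jaw_t = 12)
  ps <- project_to_plane(fs_cached, geom, grid_spacing = 1, grid_halfwidth = 10)
  cl <- collimate(ps, geom)
  out_x <- abs(ps$x) > 4 | ps$x == 4   # half-open [-4, 4)
  expect_true(all(cl$values[, out_x, ] == 0))
  expect_true(all(cl$values[, ps$x == -4, ps$y == 0] ==
                    ps$values[, ps$x == -4, ps$y == 0]))
  in_x <- ps$x > -4 & ps$x < 4
  in_y <- ps$y > -6 & ps$y < 6
  expect_equal(cl$values[, in_x, in_y], ps$values[, in_x, in_y])
  expect_equal(collimate(cl, geom)$values, cl$values)
})

test_that("the designed filter is conical, deterministic and flattens its own beam", {
  geom <- beam_geometry()
  f1 <- design_filter(6, geom, n_K = 60L, n_angle = 61L, n_slabs = 120L)
  f2 <- design_filter(6, geom, n_K = 60L, n_angle = 61L, n_slabs = 120L)
  expect_identical(f1, f2)
  expect_equal(which.max(f1$thickness), 1L)
  expect_true(all(diff(f1$thickness) <= 1e-12))
  expect_true(all(f1$thickness >= 0))
  # forward model through the filter: flat at the design energy
  fs6 <- fluence_spectrum(6, n_K = 60L, n_angle = 61L, n_slabs = 120L)
  ps <- project_to_plane(fs6, geom, grid_spacing = 0.5, grid_halfwidth = 12)
  ps <- attenuate(ps, f1, geom)
  ps <- collimate(ps, geom)
  grid <- spot_convolve(kerma_dose(ps, 1.5), 0.1, geom)
  expect_equal(flatness(grid, geom$jaw_r, "r"), 1, tolerance = 0.02)
})
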