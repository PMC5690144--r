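test_that("presets validate, match their energies, and unknown names fail", {
  p15 <- load_preset("15MV")
  p6 <- load_preset("6MV")
  expect_equal(nrow(validate_settings(p15)), 0L)
  expect_equal(nrow(validate_settings(p6)), 0L)
  expect_error(load_preset("10MV"), "6MV.*15MV")
  # the bend coil is matched: set-point equals the loaded beam energy
  for (p in list(p15, p6)) {
    p_out <- klystron_output(p$rf_drive, p$kly_voltage)
    e <- loaded_energy(p_out, gun_current(p$gun_voltage))
    expect_equal(setpoint_energy(p$bmag_current), e, tolerance = 1e-8)
  }
  # the 6 MV preset runs the klystron well below saturation
  expect_lt(klystron_output(p6$rf_drive, 125),
            klystron_output(p15$rf_drive, 125) / 2)
})

test_that("settings validation reports each out-of-range field", {
  s <- load_preset("15MV")
  s$kly_voltage <- 90
  s$jaw_r <- -1
  viol <- validate_settings(s)
  expect_setequal(viol$field, c("kly_voltage", "jaw_r"))
  expect_equal(viol$min[viol$field == "kly_voltage"], 100)
  expect_equal(viol$max[viol$field == "kly_voltage"], 145)
  expect_error(simulate_linac(s, coarse_opts), "invalid control settings")
})

test_that("the simulation is a pure function of its settings", {
  p <- load_preset("15MV")
  r1 <- simulate_linac(p, coarse_opts)
  r2 <- simulate_linac(p, coarse_opts)
  expect_identical(r1$dose_rate, r2$dose_rate)
  expect_identical(r1$dose_grid$values, r2$dose_grid$values)
  expect_lte(r1$target_current, r1$gun_current)
  expect_true(all(r1$dose_grid$values >= 0))
})

test_that("detuning the bend coil either way strictly decreases dose rate", {
  p <- load_preset("15MV")
  r0 <- simulate_linac(p, coarse_opts)$dose_rate
  for (d in c(-20, -5, 5, 20)) {
    s <- p
    s$bmag_current <- p$bmag_current + d
    expect_lt(simulate_linac(s, coarse_opts)$dose_rate, r0)
  }
})

test_that("drive, voltage and gun sweeps each show an interior dose-rate maximum", {
  p15 <- load_preset("15MV")
  interior_max <- function(rate) {
    i <- which.max(rate)
    i > 1 && i < length(rate) && rate[i] > rate[1] && rate[i] > rate[length(rate)]
  }
  rf <- sweep_parameter(p15, "rf_drive", seq(40, 100, length.out = 13),
                        coarse_opts)
  expect_true(interior_max(rf$dose_rate))
  # saturation plateau: drive changes near the operating point barely move dose
  mid <- rf$dose_rate[rf$value >= 60 & rf$value <= 80]
  expect_lt(diff(range(mid)) / max(mid), 0.1)
  kv <- sweep_parameter(p15, "kly_voltage", seq(100, 145, length.out = 13),
                        coarse_opts)
  expect_true(interior_max(kv$dose_rate))
  # gun sweep with the bend matched mid-range
  s <- p15
  s$gun_voltage <- 10
  s$bmag_current <- match_bend_current(s)$current
  gv <- sweep_parameter(s, "gun_voltage", seq(7.5, 12.5, length.out = 13),
                        coarse_opts)
  expect_true(interior_max(gv$dose_rate))
  expect_equal(gv$gun_current[1L], 115, tolerance = 1e-6)
  expect_equal(gv$gun_current[13L], 115 * (12.5 / 7.5)^1.5, tolerance = 1e-6)
  # beam loading: energy falls as gun current rises
  expect_true(all(diff(gv$beam_energy) < 0))
})

test_that("flatness falls monotonically with energy on a fixed 6 MV filter", {
  p6 <- load_preset("6MV")
  fl <- vapply(seq(4.5, 7.5, by = 0.5), function(e) {
    simulate_linac(settings_for_energy(e, p6), coarse_opts)$flatness
  }, numeric(1L))
  expect_true(all(diff(fl) < 0))
  expect_gt(fl[1L], 1)   # below design energy: over-flattened
  expect_lt(fl[7L], 1)   # above design energy: forward peaked, FFF-like
})

test_that("symmetry responds linearly to the angle steering coil", {
  p15 <- load_preset("15MV")
  cur <- c(-100, -50, 0, 50, 100)
  sy <- vapply(cur, function(a) {
    s <- p15
    s$ang_r <- a
    simulate_linac(s, coarse_opts)$symmetry_r
  }, numeric(1L))
  fit <- stats::lm(sy ~ cur)
  expect_gt(summary(fit)$r.squared, 0.99)
  expect_true(all(diff(sy) > 0) || all(diff(sy) < 0))
})

test_that("position coils move both spot and angle; empty sweeps are empty", {
  p15 <- load_preset("15MV")
  s <- p15
  s$pos_r <- 100
  rp <- simulate_linac(s, coarse_opts)
  expect_gt(abs(rp$symmetry_r), 0.1)
  tab <- sweep_parameter(p15, "rf_drive", numeric(0), coarse_opts)
  expect_s3_class(tab, "data.frame")
  expect_equal(nrow(tab), 0L)
  expect_error(sweep_parameter(p15, "nonsense", 1:3), "unknown sweep parameter")
})
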