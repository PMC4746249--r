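test_that("residual percentage normalizes by control and internal standard", {
  live <- isotope_series(time = c(0, 50), conc = c(100, 40), compound = "ethylbenzene",
    conc_control = c(100, 100))
  # single-input form: conc_control column
  curve <- residual_percentage(live)
  expect_equal(curve$residual_pct, c(100, 40))
  expect_equal(attr(curve, "normalization"), "control_only")

  # two-series form with internal standard: 100 * (36/90) / (100/100) = 40
  live2 <- isotope_series(time = c(0, 50), conc = c(100, 36), compound = "ethylbenzene",
    conc_internal_std = c(100, 90))
  ctrl2 <- isotope_series(time = c(0, 50), conc = c(100, 100), compound = "ethylbenzene",
    conc_internal_std = c(100, 100))
  curve2 <- residual_percentage(live2, ctrl2, use_internal_std = TRUE)
  expect_equal(curve2$residual_pct, c(100, 40))
  expect_equal(attr(curve2, "normalization"), "control_and_internal_std")

  # equal live and control: 100% everywhere
  same <- residual_percentage(live2, live2, use_internal_std = TRUE)
  expect_equal(same$residual_pct, c(100, 100))
})

test_that("residual percentage is scale invariant and refuses misaligned times", {
  live <- isotope_series(time = c(0, 30, 60), conc = c(80, 50, 10), compound = "benzene",
    conc_internal_std = c(95, 90, 85))
  ctrl <- isotope_series(time = c(0, 30, 60), conc = c(82, 78, 74), compound = "benzene",
    conc_internal_std = c(96, 92, 88))
  base <- residual_percentage(live, ctrl, use_internal_std = TRUE)

  # multiplying all live concentrations (target and IS) by a constant
  # leaves the curve unchanged
  live_scaled <- isotope_series(time = live$time, conc = live$conc * 3.7,
    compound = "benzene", conc_internal_std = live$conc_internal_std * 3.7)
  scaled <- residual_percentage(live_scaled, ctrl, use_internal_std = TRUE)
  expect_equal(scaled$residual_pct, base$residual_pct, tolerance = 1e-12)

  ctrl_shift <- isotope_series(time = c(0, 30, 61), conc = ctrl$conc, compound = "benzene")
  expect_error(residual_percentage(live, ctrl_shift), class = "csiaray_input_error")

  ctrl_zero <- isotope_series(time = ctrl$time, conc = c(82, 0, 74), compound = "benzene")
  expect_error(residual_percentage(live, ctrl_zero), class = "csiaray_domain_error")
})

test_that("lag detection finds the first sustained sub-threshold time", {
  flat <- raw_curve(seq(0, 90, by = 10), rep(100, 10))
  expect_true(is.na(detect_lag(flat)))

  # hand-applied rule on a 10-point fixture: flat at 100 until day 60,
  # then monotone decline; first sub-95% samples are days 70, 80, 90
  curve <- raw_curve(seq(0, 90, by = 10), c(100, 100, 100, 100, 100, 100, 99, 90, 70, 40))
  expect_equal(detect_lag(curve, threshold_pct = 5, sustain_points = 2), 70)
  # a stricter threshold can only push the lag later
  expect_equal(detect_lag(curve, threshold_pct = 25, sustain_points = 2), 80)
  for (th in c(1, 5, 10, 25, 50)) {
    expect_true(is.na(detect_lag(curve, th)) ||
      detect_lag(curve, th) >= detect_lag(curve, 1))
  }

  # zero threshold: first strictly sub-100 sustained point (day 60 at 99%)
  expect_equal(detect_lag(curve, threshold_pct = 0), 60)

  expect_error(detect_lag(raw_curve(c(0, 10), c(100, 90)), sustain_points = 2),
    class = "csiaray_precondition_error")
})

test_that("halt detection flags plateaus before complete removal only", {
  # built to plateau at 40% residual -> 60% removal halt
  halt_curve <- raw_curve(seq(0, 120, by = 15),
    c(100, 100, 80, 60, 40.2, 40.1, 40.0, 39.9, 40.0))
  res <- detect_halt(halt_curve)
  expect_true(res$halted)
  expect_equal(res$halt_extent_pct, 60, tolerance = 1)
  expect_false(res$low_confidence)

  # monotone decline to zero: never flags during the decline
  mono <- raw_curve(seq(0, 120, by = 15), c(100, 88, 70, 52, 35, 20, 10, 4, 1))
  expect_false(detect_halt(mono)$halted)

  # never started: constant 100%
  expect_false(detect_halt(raw_curve(seq(0, 60, by = 10), rep(100, 7)))$halted)

  # too few points: not halted, low confidence
  short <- detect_halt(raw_curve(c(0, 10), c(100, 60)), window_points = 3)
  expect_false(short$halted)
  expect_true(short$low_confidence)
})

test_that("halt detection never fires on noiseless uninhibited simulator output", {
  cfg <- btex_scenario()
  cfg$sigma_conc_rel <- 0
  cfg$sigma_delta13C <- 0
  cfg$sigma_delta2H <- 0
  sim <- simulate_microcosm(cfg)
  for (nm in c("ethylbenzene", "toluene", "benzene")) {
    curve <- residual_percentage(sim$live[[nm]], sim$control[[nm]], use_internal_std = TRUE)
    expect_false(detect_halt(curve)$halted, label = nm)
  }
})

test_that("an inhibited simulation is reported as halted at its removal extent", {
  cfg <- btex_scenario()
  cfg$sigma_conc_rel <- 0
  # molybdate-style instantaneous stop during ethylbenzene removal:
  # f_bio frozen at exp(-0.06 * (65 - 50)) = 0.407 -> ~59% removal
  cfg$inhibition_time <- 65
  sim <- simulate_microcosm(cfg)
  curve <- residual_percentage(sim$live$ethylbenzene, sim$control$ethylbenzene,
    use_internal_std = TRUE)
  res <- detect_halt(curve)
  expect_true(res$halted)
  expect_equal(res$halt_extent_pct, 100 * (1 - exp(-0.06 * 15)), tolerance = 1)
  ks <- kinetics_summary(curve)
  expect_true(ks$halted)
  expect_equal(ks$removal_extent_pct, 100 * (1 - exp(-0.06 * 15)), tolerance = 0.5)
})

test_that("doubling time follows log-linear growth", {
  expect_equal(doubling_time(1e6, 2e6, 20), 20)
  expect_equal(doubling_time(1e6, 4e6, 40), 20) # two doublings
  expect_equal(doubling_time(3.6e6, 1.2e7, 35), 35 * log(2) / log(1.2e7 / 3.6e6),
    tolerance = 1e-12)
  expect_equal(doubling_time(3.6e6, 1.2e7, 35), 20.15, tolerance = 0.005)
  expect_error(doubling_time(2e6, 1e6, 10), class = "csiaray_domain_error")
  expect_error(doubling_time(0, 1e6, 10), class = "csiaray_domain_error")
})
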