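test_that("biosensor ratio reproduces the dual-excitation worked example", {
  r <- biosensor_ratio(
    list(excitation_nm = 454, emission_nm = 630, intensity = 5.8e6),
    list(excitation_nm = 580, emission_nm = 630, intensity = 6.8e6)
  )
  expect_equal(round(r$value, 2), 0.85)
  expect_equal(r$numerator_exc_nm, 454)
  expect_equal(r$denominator_exc_nm, 580)

  same <- biosensor_ratio(
    list(excitation_nm = 380, emission_nm = 510, intensity = 1234),
    list(excitation_nm = 470, emission_nm = 510, intensity = 1234)
  )
  expect_equal(same$value, 1)
})

test_that("biosensor ratio is scale invariant and validates its inputs", {
  set.seed(21)
  for (i in 1:20) {
    a <- runif(1, 1, 1e7)
    b <- runif(1, 1, 1e7)
    cc <- runif(1, 1e-3, 1e3)
    r1 <- biosensor_ratio(
      list(excitation_nm = 380, emission_nm = 510, intensity = a),
      list(excitation_nm = 470, emission_nm = 510, intensity = b)
    )$value
    r2 <- biosensor_ratio(
      list(excitation_nm = 380, emission_nm = 510, intensity = cc * a),
      list(excitation_nm = 470, emission_nm = 510, intensity = cc * b)
    )$value
    expect_equal(r2, r1, tolerance = 1e-12)
  }
  expect_error(
    biosensor_ratio(
      list(excitation_nm = 454, emission_nm = 630, intensity = 1),
      list(excitation_nm = 580, emission_nm = 620, intensity = 1)
    ),
    class = "platesensor_ratio_error"
  )
  expect_error(
    biosensor_ratio(
      list(excitation_nm = 454, emission_nm = 630, intensity = 1),
      list(excitation_nm = 580, emission_nm = 630, intensity = 0)
    ),
    class = "platesensor_ratio_error"
  )
})

test_that("peak detection matches a brute-force argmax oracle", {
  s <- sensor_mcherry_ea()
  scan <- render_excitation_scan(s, I_a = 2e6, I_b = 3e6, step_nm = 1)
  pk <- find_excitation_peaks(scan, smooth_window_pts = 3)
  # noiseless two-Gaussian scan: smoothed argmax equals raw argmax
  expect_equal(pk$peak_nm, scan$excitation_nm[which.max(scan$intensity)])

  increasing <- tibble::tibble(excitation_nm = 400:500, intensity = seq(1, 2, length.out = 101))
  expect_error(
    find_excitation_peaks(increasing, require_local_max = TRUE),
    class = "platesensor_scan_error"
  )
  expect_error(
    find_excitation_peaks(scan, windows = list(c(100, 200))),
    class = "platesensor_scan_error"
  )
})

test_that("oxidation degree is 0 at the reduced and 1 at the oxidized control", {
  set.seed(31)
  for (i in 1:50) {
    I470_red <- runif(1, 10, 1e6)
    I470_ox <- runif(1, 10, 1e6)
    r_red <- runif(1, 0.2, 0.9)
    r_ox <- r_red + runif(1, 0.2, 1.5)
    ctl <- redox_controls(r_red * I470_red, I470_red, r_ox * I470_ox, I470_ox)
    expect_equal(oxidation_degree(ctl$I380_red, ctl$I470_red, ctl)$oxd, 0, tolerance = 1e-12)
    expect_equal(oxidation_degree(ctl$I380_ox, ctl$I470_ox, ctl)$oxd, 1, tolerance = 1e-12)
  }
  expect_error(redox_controls(1.4, 1, 0.53, 1), class = "platesensor_oxd_error")
})

test_that("intensity and ratio forms of the oxidation degree agree on 1000 random tuples", {
  set.seed(32)
  n <- 1000
  I470_red <- runif(n, 1e2, 1e6)
  I470_ox <- runif(n, 1e2, 1e6)
  r_red <- runif(n, 0.2, 0.9)
  r_ox <- r_red + runif(n, 0.2, 1.5)
  I470_s <- runif(n, 1e2, 1e6)
  r_s <- r_red + runif(n, 0, 1) * (r_ox - r_red) # samples between the controls
  worst <- 0
  for (i in seq_len(n)) {
    ctl <- redox_controls(
      r_red[i] * I470_red[i], I470_red[i],
      r_ox[i] * I470_ox[i], I470_ox[i]
    )
    a <- oxidation_degree(r_s[i] * I470_s[i], I470_s[i], ctl)$oxd
    b <- oxd_from_ratios(r_s[i], r_red[i], r_ox[i], alpha = I470_ox[i] / I470_red[i])$oxd
    worst <- max(worst, abs(a - b))
  }
  expect_lt(worst, 1e-12)
})

test_that("oxidation degree is brightness invariant and monotone in the sample ratio", {
  ctl <- redox_controls(0.53, 1, 0.98, 0.7)
  set.seed(33)
  for (i in 1:20) {
    I380 <- runif(1, 1, 1e5)
    I470 <- runif(1, 1, 1e5)
    k <- runif(1, 1e-3, 1e3)
    expect_equal(
      oxidation_degree(k * I380, k * I470, ctl)$oxd,
      oxidation_degree(I380, I470, ctl)$oxd,
      tolerance = 1e-12
    )
  }
  rs <- seq(0.54, 1.39, length.out = 50)
  oxds <- oxd_from_ratios(rs, 0.53, 1.4, alpha = 0.7)$oxd
  expect_true(all(diff(oxds) > 0))
  expect_error(oxd_from_ratios(0.8, 1.4, 0.53, 0.7), class = "platesensor_oxd_error")
})

test_that("out-of-range oxidation degrees are flagged, not clamped by default", {
  ctl <- redox_controls(0.53, 1, 0.98, 0.7)
  res <- oxidation_degree(0.50, 1, ctl) # slightly below the reduced control
  expect_lt(res$oxd, 0)
  expect_false(res$in_range)
})

test_that("two-point pH calibration has the closed-form slope and inverts exactly", {
  curve <- fit_ph_calibration(data.frame(ph = c(7.0, 8.5), ratio = c(0.85, 1.35)))
  expect_equal(curve$slope, 0.5 / 1.5, tolerance = 1e-12)
  expect_equal(curve$r_squared, 1)
  expect_equal(ratio_to_ph(curve, 0.85)$ph, 7.0, tolerance = 1e-12)
  expect_equal(ratio_to_ph(curve, 1.35)$ph, 8.5, tolerance = 1e-12)

  # collinear standards at 4 pH values
  ph <- c(7, 7.5, 8, 8.5)
  curve2 <- fit_ph_calibration(data.frame(ph = ph, ratio = 0.3 * ph - 1.25))
  expect_equal(curve2$r_squared, 1, tolerance = 1e-12)
  set.seed(34)
  x <- runif(5, 6.5, 9)
  expect_equal(ratio_to_ph(curve2, 0.3 * x - 1.25, warn_extrapolation = FALSE)$ph, x,
    tolerance = 1e-9
  )

  expect_error(
    fit_ph_calibration(data.frame(ph = c(7, 7), ratio = c(0.8, 0.9))),
    class = "platesensor_calibration_error"
  )
  expect_warning(ratio_to_ph(curve, 2.5), "extrapolation")
})

test_that("predicted pH is strictly monotone in the ratio", {
  curve <- fit_ph_calibration(data.frame(ph = c(7.0, 8.5), ratio = c(0.85, 1.35)))
  ratios <- seq(0.85, 1.35, length.out = 20)
  expect_true(all(diff(ratio_to_ph(curve, ratios, warn_extrapolation = FALSE)$ph) > 0))
})

test_that("colony maps are plate-oriented with span statistics over samples", {
  # constant-truth plate: range 0
  lay <- tibble::tibble(well = well_labels(96)[1:24], role = "sample", ph = 7.5)
  g <- simulate_ph_plate(lay, noise = noiseless())
  cm <- colony_map(g, "ratio")
  expect_equal(cm$summary$range, 0, tolerance = 1e-12)
  expect_equal(dim(cm$values), c(8, 12))
  expect_equal(cm$values["A", "1"], cm$data$value[cm$data$well == "A1"])
  expect_equal(sum(is.finite(cm$values)), 24)

  # span comparison between a wide and a narrow per-colony pH distribution
  wide <- summarize_wells(c(7.26, 7.5, 7.82))
  narrow <- summarize_wells(c(7.59, 7.7, 7.76))
  expect_equal(wide$range, 0.56)
  expect_equal(narrow$range, 0.17)
  expect_equal(wide$range - narrow$range, 0.39)
})

test_that("simulated pH plates are recovered within the reader's per-colony accuracy", {
  wells <- well_labels(384)
  set.seed(41)
  lay <- tibble::tibble(
    well = wells[1:132],
    role = c(rep("ph_standard", 12), rep("sample", 120)),
    role_value = c(rep(c(7, 7.5, 8, 8.5), each = 3), rep(NA, 120)),
    ph = c(rep(NA, 12), rnorm(120, 7.65, 0.03)),
    brightness = runif(132, 0.8, 1.2)
  )
  g <- simulate_ph_plate(lay,
    noise = noise_model(cv = 0.02, channel_cv = 0.005, seed = 11),
    format = 384
  )
  res <- plate_ph(g)
  truth <- lay$ph[match(res$well, lay$well)]
  expect_lt(abs(mean(res$ph) - mean(truth)), 0.01)
  expect_gte(mean(abs(res$ph - truth) <= 0.05), 0.95)
  # recovered span reflects the simulated spread, not noise blow-up
  expect_lt(summarize_wells(res$ph)$range, 2 * diff(range(truth)))
})
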