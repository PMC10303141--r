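test_that("identical seed and configuration give byte-identical plate CSVs", {
  lay <- tibble::tibble(
    well = well_labels(96)[1:10],
    role = c("reduced_control", "oxidized_control", rep("sample", 8)),
    oxd = c(NA, NA, seq(0.1, 0.8, 0.1))
  )
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_plate_csv(simulate_redox_plate(lay, noise = noise_model(seed = 5)), f1)
  write_plate_csv(simulate_redox_plate(lay, noise = noise_model(seed = 5)), f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_plate_csv(simulate_redox_plate(lay, noise = noise_model(seed = 6)), f3)
  expect_false(identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f3))))
})

test_that("noiseless simulated intensities invert exactly through the OxD equation", {
  oxd_true <- seq(0, 1, by = 0.1)
  lay <- tibble::tibble(
    well = well_labels(96)[seq_along(oxd_true) + 2],
    role = "sample", oxd = oxd_true
  )
  lay <- dplyr::bind_rows(
    tibble::tibble(well = c("A1", "A2"), role = c("reduced_control", "oxidized_control"), oxd = NA),
    lay
  )
  g <- simulate_redox_plate(lay, noise = noiseless())
  est <- plate_oxd(g)
  expect_lt(max(abs(est$oxd - oxd_true)), 1e-12)

  expect_error(
    simulate_redox_plate(
      tibble::tibble(well = "A1", role = "sample", oxd = 1.2),
      noise = noiseless()
    ),
    class = "platesensor_sensor_error"
  )
})

test_that("two-state endpoints reproduce the control ratios exactly", {
  s <- sensor_mrx1_rogfp2()
  mix <- sensor_intensities(s, c(0, 1))
  expect_equal(mix$ratio, c(0.53, 1.4), tolerance = 1e-12)
})

test_that("pH plate anchors and midpoint follow the linear ratio model", {
  lay <- tibble::tibble(well = c("A1", "A2", "A3"), role = "sample", ph = c(7.0, 8.5, 7.75))
  g <- simulate_ph_plate(lay, noise = noiseless())
  r <- plate_ratios(g, 454, 580)
  expect_equal(r$ratio[match(c("A1", "A2", "A3"), r$well)], c(0.85, 1.35, 1.10),
    tolerance = 1e-12
  )
  expect_error(
    simulate_ph_plate(lay, anchors = c(8.5, 0.85, 7.0, 1.35), noise = noiseless()),
    class = "platesensor_sensor_error"
  )
  expect_warning(
    simulate_ph_plate(
      tibble::tibble(well = "A1", role = "sample", ph = 6.0),
      noise = noiseless()
    ),
    "extrapolat"
  )
})

test_that("noiseless calibration and inversion recover the input pH", {
  lay <- tibble::tibble(
    well = well_labels(96)[1:16],
    role = c(rep("ph_standard", 4), rep("sample", 12)),
    role_value = c(7, 7.5, 8, 8.5, rep(NA, 12)),
    ph = c(rep(NA, 4), seq(7.05, 8.45, length.out = 12))
  )
  g <- simulate_ph_plate(lay, noise = noiseless())
  res <- plate_ph(g)
  expect_lt(max(abs(res$ph - lay$ph[5:16])), 1e-9)
})

test_that("TFB simulation matches the Hill identities", {
  m <- tfb_model(F0 = 5e3, Fmax = 1.95e5, K = 0.1, n = 1.5)
  expect_equal(hill_response(0, m), 5e3)
  expect_equal(hill_response(0.1, m), 5e3 + 1.95e5 / 2)
  expect_lt(abs(hill_response(100, m) - (5e3 + 1.95e5)) / (5e3 + 1.95e5), 0.01)

  lay <- tibble::tibble(well = c("A1", "A2"), strain = "ev", dose = c(0, 5), role = "sample")
  g <- simulate_tfb_plate(lay, models = list(ev = tfb_model(Fmax = 0)), noise = noiseless())
  expect_equal(unique(g$intensity), 4.96e3) # flat empty-vector response
})

test_that("kinetic traces relax exponentially after treatment", {
  tau <- 90
  tr <- simulate_kinetic_trace(
    oxd_pre = 0.4, oxd_post = 0.4, treatment_time_s = 300,
    relaxation_tau_s = tau, noise = noiseless()
  )
  expect_equal(length(unique(tr$intensity[tr$excitation_nm == 380])), 1) # flat control

  tr2 <- simulate_kinetic_trace(
    oxd_pre = 0.8, oxd_post = 0.1, treatment_time_s = 300,
    relaxation_tau_s = tau, duration_s = 1200, dt_s = 30, noise = noiseless()
  )
  kt <- trace_from_readings(tr2)
  # at t0 + 5 tau the state has relaxed to within exp(-5) < 0.7% of the step
  r_at <- kt$ratio[kt$time_s == 300 + 5 * tau]
  r_post <- sensor_intensities(sensor_mrx1_rogfp2(), 0.1)$ratio
  r_pre <- sensor_intensities(sensor_mrx1_rogfp2(), 0.8)$ratio
  expect_lt(abs(r_at - r_post) / abs(r_pre - r_post), 0.007 * 2) # ratio is mildly nonlinear in OxD

  cls <- classify_redox_response(trace_from_readings(
    simulate_kinetic_trace(
      oxd_pre = 0.3524, oxd_post = 0,
      noise = noise_model(cv = 0.01, channel_cv = 0.005, seed = 2)
    )
  ))
  expect_equal(cls$call, "reduced")
})

test_that("dilution series shrinks geometrically with a size-invariant ratio", {
  strains <- tibble::tibble(strain = c("wt_sensor", "mut_sensor"), ratio = c(1.05, 1.45))
  g <- simulate_dilution_series(strains, n_steps = 3, noise = noiseless())
  sizes <- dplyr::distinct(tibble::as_tibble(g), well, strain, dose, size_px)
  wt <- dplyr::arrange(dplyr::filter(sizes, strain == "wt_sensor"), dose)
  expect_equal(100 * wt$size_px / wt$size_px[1], c(100, 90, 81, 72.9), tolerance = 1e-9)

  r <- plate_ratios(g, 380, 470)
  for (s in strains$strain) {
    expect_equal(diff(range(r$ratio[r$strain == s])), 0, tolerance = 1e-12)
  }
  # intensities scale linearly with area, ratio untouched (random loss rates)
  set.seed(7)
  for (loss in runif(4, 0.05, 0.5)) {
    g2 <- simulate_dilution_series(strains,
      n_steps = 2, size_loss_per_step = loss,
      noise = noiseless()
    )
    r2 <- plate_ratios(g2, 380, 470)
    for (s in strains$strain) {
      rs <- dplyr::arrange(dplyr::filter(r2, strain == s), dose)
      expect_equal(rs$I_den / rs$I_den[1], (1 - loss)^(0:2), tolerance = 1e-9)
      expect_equal(rs$I_num / rs$I_num[1], (1 - loss)^(0:2), tolerance = 1e-9)
      expect_equal(diff(range(rs$ratio)), 0, tolerance = 1e-12)
    }
  }
})

test_that("synthetic excitation scans peak at the sensor band centers", {
  s <- sensor_mcherry_ea()
  scan <- render_excitation_scan(s, I_a = 5.8e6, I_b = 6.8e6)
  peaks <- find_excitation_peaks(scan, windows = list(c(430, 480), c(550, 590)))
  expect_equal(peaks$peak_nm, c(454, 580))
  # band amplitudes survive at the peaks (bands well separated)
  expect_equal(peaks$intensity, c(5.8e6, 6.8e6), tolerance = 0.02)

  # single-band-like model: one dominant peak in its window
  scan2 <- render_excitation_scan(
    two_state_sensor(500, 900, 630, 1, 1, 1.5, 1),
    I_a = 1e6, I_b = 0.0001
  )
  pk <- find_excitation_peaks(scan2, require_local_max = TRUE)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$peak_nm, 500)
})
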