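#' Simulate a redox-sensor plate
#'
#' Generates endpoint channel readings (excitation `channel_a`/`channel_b`,
#' shared emission) for arrayed colonies carrying a two-state redox sensor.
#' Noiseless intensities are the linear two-state mixture
#' `I_ch = brightness * ((1 - OxD) * I_ch_red + OxD * I_ch_ox)`; noise is then
#' applied per [noise_model()]. Wells with role `reduced_control` /
#' `oxidized_control` are emitted at OxD 0 / 1; `blank` wells carry background
#' only.
#'
#' @param layout A layout tibble (see [apply_layout()]) with additional numeric
#'   columns `oxd` (true oxidation degree of sample wells, in `[0, 1]`) and
#'   optionally `brightness` (default 1).
#' @param sensor A [two_state_sensor()]; defaults to [sensor_mrx1_rogfp2()].
#' @param noise A [noise_model()].
#' @param plate_id Plate identifier.
#' @param format Plate format.
#' @return An annotated [plate_grid()].
#' @export
simulate_redox_plate <- function(layout, sensor = sensor_mrx1_rogfp2(),
                                 noise = noise_model(), plate_id = "sim-redox",
                                 format = 96) {
  layout <- read_layout(layout)
  if (!"role" %in% names(layout)) layout$role <- "sample"
  if (!"brightness" %in% names(layout)) layout$brightness <- 1
  oxd <- dplyr::case_when(
    layout$role == "reduced_control" ~ 0,
    layout$role == "oxidized_control" ~ 1,
    layout$role == "blank" ~ NA_real_,
    TRUE ~ layout$oxd
  )
  active <- layout$role != "blank"
  if (any(!is.finite(oxd[active]))) {
    abort("Every non-blank well needs a finite `oxd`.", class = "platesensor_sensor_error")
  }
  if (any(oxd[active] < 0 | oxd[active] > 1)) {
    abort("`oxd` must lie in [0, 1].", class = "platesensor_sensor_error")
  }
  I_a <- I_b <- numeric(nrow(layout))
  mix <- sensor_intensities(sensor, oxd[active], layout$brightness[active])
  I_a[active] <- mix$I_a
  I_b[active] <- mix$I_b
  readings <- tibble(
    well = rep(layout$well, each = 2),
    excitation_nm = rep(c(sensor$channel_a, sensor$channel_b), nrow(layout)),
    emission_nm = sensor$emission_nm,
    time_s = NA_real_,
    intensity = as.vector(rbind(I_a, I_b))
  )
  readings <- with_seed(noise$seed, apply_noise(readings, noise, unit = readings$well))
  grid <- plate_grid(readings, plate_id = plate_id, format = format)
  apply_layout(grid, layout[, intersect(names(layout), c("well", layout_columns))])
}

#' Simulate a pH-sensor plate
#'
#' The noiseless 454/580-type biosensor ratio is linear in pH through two
#' anchor points; the reference channel intensity equals the colony
#' brightness and the state channel is `brightness * ratio(pH)`. Wells with
#' role `ph_standard` are emitted at their `role_value` pH (the in-colony
#' calibration standards produced by CTAB permeabilization at a set buffer
#' pH).
#'
#' @param layout Layout tibble with numeric column `ph` for sample wells and
#'   optionally `brightness`.
#' @param anchors Numeric vector `c(ph_lo, ratio_lo, ph_hi, ratio_hi)`; the
#'   defaults are the plate-reader calibration anchors (ratio 0.85 at pH 7.0,
#'   1.35 at pH 8.5).
#' @param sensor A [two_state_sensor()] supplying the channel wavelengths.
#' @param noise A [noise_model()].
#' @param plate_id,format Plate identifier and format.
#' @return An annotated [plate_grid()].
#' @export
simulate_ph_plate <- function(layout, anchors = c(7.0, 0.85, 8.5, 1.35),
                              sensor = sensor_mcherry_ea(),
                              noise = noise_model(), plate_id = "sim-ph",
                              format = 96) {
  stopifnot(length(anchors) == 4)
  ph_lo <- anchors[1]
  r_lo <- anchors[2]
  ph_hi <- anchors[3]
  r_hi <- anchors[4]
  if (ph_lo >= ph_hi) {
    abort("Anchor pH span is empty (ph_lo >= ph_hi).", class = "platesensor_sensor_error")
  }
  layout <- read_layout(layout)
  if (!"role" %in% names(layout)) layout$role <- "sample"
  if (!"brightness" %in% names(layout)) layout$brightness <- 1
  if (!"ph" %in% names(layout)) layout$ph <- NA_real_
  ph <- ifelse(layout$role == "ph_standard", layout$role_value, layout$ph)
  active <- layout$role != "blank"
  if (any(!is.finite(ph[active]))) {
    abort("Every non-blank well needs a finite `ph` (or ph_standard role_value).",
      class = "platesensor_sensor_error"
    )
  }
  if (any(ph[active] < ph_lo | ph[active] > ph_hi)) {
    warn("Some pH values lie outside the anchor span; ratios are extrapolated.")
  }
  slope <- (r_hi - r_lo) / (ph_hi - ph_lo)
  ratio <- r_lo + slope * (ph - ph_lo)
  I_b <- ifelse(active, layout$brightness, 0)
  I_a <- ifelse(active, layout$brightness * ratio, 0)
  readings <- tibble(
    well = rep(layout$well, each = 2),
    excitation_nm = rep(c(sensor$channel_a, sensor$channel_b), nrow(layout)),
    emission_nm = sensor$emission_nm,
    time_s = NA_real_,
    intensity = as.vector(rbind(I_a, I_b))
  )
  readings <- with_seed(noise$seed, apply_noise(readings, noise, unit = readings$well))
  grid <- plate_grid(readings, plate_id = plate_id, format = format)
  apply_layout(grid, layout[, intersect(names(layout), c("well", layout_columns))])
}

#' Simulate a transcription-factor-biosensor dose-response plate
#'
#' Single-channel endpoint fluorescence per colony following the Hill
#' dose-response of the strain's reporter construct.
#'
#' @param layout Layout tibble with columns `well`, `strain`, `dose` (inducer
#'   concentration, e.g. mM IPTG) and optionally `brightness`.
#' @param models Named list mapping each strain to a [tfb_model()].
#' @param excitation_nm,emission_nm Reader wavelengths (mCherry defaults).
#' @param noise A [noise_model()].
#' @param plate_id,format Plate identifier and format.
#' @return An annotated [plate_grid()].
#' @export
simulate_tfb_plate <- function(layout, models,
                               excitation_nm = 580, emission_nm = 620,
                               noise = noise_model(), plate_id = "sim-tfb",
                               format = 96) {
  layout <- read_layout(layout)
  if (!"role" %in% names(layout)) layout$role <- "sample"
  if (!"brightness" %in% names(layout)) layout$brightness <- 1
  missing_models <- setdiff(unique(layout$strain), names(models))
  if (length(missing_models) > 0) {
    abort(paste0("No tfb_model for strain(s): ", paste(missing_models, collapse = ", ")),
      class = "platesensor_sensor_error"
    )
  }
  intensity <- purrr::map_dbl(seq_len(nrow(layout)), function(i) {
    hill_response(layout$dose[i], models[[layout$strain[i]]]) * layout$brightness[i]
  })
  readings <- tibble(
    well = layout$well,
    excitation_nm = excitation_nm,
    emission_nm = emission_nm,
    time_s = NA_real_,
    intensity = intensity
  )
  readings <- with_seed(noise$seed, apply_noise(readings, noise, unit = readings$well))
  grid <- plate_grid(readings, plate_id = plate_id, format = format)
  apply_layout(grid, layout[, intersect(names(layout), c("well", layout_columns))])
}

#' Simulate a kinetic treatment-response trace
#'
#' Channel readings of one colony followed in real time through a treatment
#' (reductant/oxidant/buffer drop) applied at `treatment_time_s`. The
#' oxidation degree holds at `oxd_pre` before treatment and relaxes
#' exponentially to `oxd_post` with time constant `relaxation_tau_s`
#' afterwards. A buffer-only control can be emulated with
#' `oxd_post = oxd_pre` plus a transient pulse (`transient_delta`, an
#' alpha-function excursion peaking `transient_tau_s` after treatment).
#' In kinetic mode the common-mode noise factor is redrawn per timepoint.
#'
#' @param sensor A [two_state_sensor()].
#' @param oxd_pre,oxd_post Oxidation degrees in `[0, 1]`.
#' @param treatment_time_s Treatment time (s), within the trace.
#' @param relaxation_tau_s Relaxation time constant (s), `> 0`.
#' @param duration_s,dt_s Trace length and sampling interval (s).
#' @param brightness Colony brightness scale.
#' @param noise A [noise_model()].
#' @param transient_delta,transient_tau_s Optional transient pulse in OxD
#'   units (buffer-control analogue).
#' @param label Treatment label carried on the output.
#' @return A tibble of channel readings (`time_s`, `excitation_nm`,
#'   `emission_nm`, `intensity`) with attributes `treatment_time_s`, `label`.
#' @export
simulate_kinetic_trace <- function(sensor = sensor_mrx1_rogfp2(),
                                   oxd_pre, oxd_post,
                                   treatment_time_s = 300,
                                   relaxation_tau_s = 90,
                                   duration_s = 1500, dt_s = 20,
                                   brightness = 1,
                                   noise = noise_model(cv = 0.01),
                                   transient_delta = 0, transient_tau_s = 60,
                                   label = "treatment") {
  if (relaxation_tau_s <= 0 || dt_s <= 0 || duration_s <= 0) {
    abort("Times must be positive.", class = "platesensor_sensor_error")
  }
  times <- seq(0, duration_s, by = dt_s)
  u <- pmax(times - treatment_time_s, 0)
  after <- times >= treatment_time_s
  oxd <- ifelse(after,
    oxd_post + (oxd_pre - oxd_post) * exp(-u / relaxation_tau_s),
    oxd_pre
  )
  if (transient_delta != 0) {
    pulse <- transient_delta * (u / transient_tau_s) * exp(1 - u / transient_tau_s)
    oxd <- oxd + ifelse(after, pulse, 0)
  }
  oxd <- pmin(pmax(oxd, 0), 1)
  mix <- sensor_intensities(sensor, oxd, brightness)
  readings <- tibble(
    time_s = rep(times, each = 2),
    excitation_nm = rep(c(sensor$channel_a, sensor$channel_b), length(times)),
    emission_nm = sensor$emission_nm,
    intensity = as.vector(rbind(mix$I_a, mix$I_b))
  )
  readings <- with_seed(
    noise$seed,
    apply_noise(readings, noise, unit = readings$time_s)
  )
  structure(readings, treatment_time_s = treatment_time_s, label = label)
}

#' Simulate a colony dilution series
#'
#' Emulates robotic spotting of a strain dilution series: the colony area
#' shrinks geometrically by `size_loss_per_step` per dilution step, absolute
#' channel intensities scale linearly with area, and the noiseless biosensor
#' ratio is constant across steps (size invariance by construction). Strains
#' are laid out one per row, steps along columns.
#'
#' @param strains Tibble with columns `strain`, `ratio` (constant biosensor
#'   ratio of that strain) and optionally `i_b_step0` (reference-channel
#'   intensity of the undiluted colony; default `1.3e7`).
#' @param n_steps Number of dilution steps after the undiluted spot (a series
#'   `OD 10^1 ... 10^-3` has 4 steps, 5 spots).
#' @param size0_px Area of the undiluted colony (pixels).
#' @param size_loss_per_step Fractional area loss per step, in `(0, 1)`.
#' @param sensor Supplies channel wavelengths.
#' @param noise A [noise_model()] (the common-mode `cv` is also applied to the
#'   colony area).
#' @param plate_id,format Plate identifier and format.
#' @return An annotated [plate_grid()] with `dose` holding the step index and
#'   `size_px`/`perimeter_px` the (noisy) colony size.
#' @export
simulate_dilution_series <- function(strains, n_steps = 4, size0_px = 680,
                                     size_loss_per_step = 0.1,
                                     sensor = sensor_mrx1_rogfp2(),
                                     noise = noise_model(),
                                     plate_id = "sim-dilution", format = 96) {
  if (size_loss_per_step <= 0 || size_loss_per_step >= 1) {
    abort("`size_loss_per_step` must be in (0, 1).", class = "platesensor_sensor_error")
  }
  strains <- as_tibble(strains)
  if (!"i_b_step0" %in% names(strains)) strains$i_b_step0 <- 1.3e7
  steps <- 0:n_steps
  layout <- tidyr::crossing(
    dplyr::mutate(strains, .row = dplyr::row_number() - 1L),
    tibble(step = steps)
  )
  layout$well <- format_well_label(layout$.row, layout$step, format)
  layout$condition <- paste0("step", layout$step)
  layout$dose <- layout$step
  layout$role <- "sample"
  area <- size0_px * (1 - size_loss_per_step)^layout$step
  area_noisy <- with_seed(
    noise$seed + 1L,
    pmax(area * stats::rnorm(length(area), 1, noise$cv), 1)
  )
  layout$size_px <- area_noisy
  layout$perimeter_px <- 2 * sqrt(pi * area_noisy)
  scale <- area / size0_px
  I_b <- layout$i_b_step0 * scale
  I_a <- layout$ratio * I_b
  readings <- tibble(
    well = rep(layout$well, each = 2),
    excitation_nm = rep(c(sensor$channel_a, sensor$channel_b), nrow(layout)),
    emission_nm = sensor$emission_nm,
    time_s = NA_real_,
    intensity = as.vector(rbind(I_a, I_b))
  )
  readings <- with_seed(noise$seed, apply_noise(readings, noise, unit = readings$well))
  grid <- plate_grid(readings, plate_id = plate_id, format = format)
  apply_layout(grid, layout[, intersect(names(layout), c("well", layout_columns))])
}

#' Render a synthetic excitation scan
#'
#' Sum of two Gaussian excitation bands centered on the sensor's two channels
#' with the supplied amplitudes, sampled over a wavelength range (the 400 to
#' 590 nm scan at 630 nm emission used for mCherryEA-type sensors).
#'
#' @param sensor A [two_state_sensor()] (band centers and width).
#' @param I_a,I_b Band amplitudes (channel intensities of the scanned colony).
#' @param lambda_min,lambda_max,step_nm Scan range and step (nm), `step_nm > 0`.
#' @param noise A [noise_model()]; per-point noise uses `channel_cv`.
#' @return An `excitation_scan` tibble (`excitation_nm`, `intensity`) with an
#'   `emission_nm` attribute.
#' @export
render_excitation_scan <- function(sensor, I_a, I_b,
                                   lambda_min = 400, lambda_max = 590,
                                   step_nm = 2,
                                   noise = noise_model(cv = 0, channel_cv = 0)) {
  if (step_nm <= 0) abort("`step_nm` must be positive.", class = "platesensor_sensor_error")
  lambda <- seq(lambda_min, lambda_max, by = step_nm)
  if (length(lambda) < 3) {
    abort("Scan needs at least 3 points.", class = "platesensor_sensor_error")
  }
  band <- function(center, amp) amp * exp(-((lambda - center)^2) / (2 * sensor$band_sigma_nm^2))
  intensity <- band(sensor$channel_a, I_a) + band(sensor$channel_b, I_b)
  scan <- tibble(excitation_nm = lambda, intensity = intensity)
  scan <- with_seed(noise$seed, {
    g <- pmax(stats::rnorm(nrow(scan), 1, noise$channel_cv), 0)
    scan$intensity <- pmax(scan$intensity * g + noise_background(noise, scan$excitation_nm), 0)
    scan
  })
  structure(scan, emission_nm = sensor$emission_nm, class = c("excitation_scan", class(scan)))
}
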