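#' Two-state ratiometric sensor model
#'
#' Photophysical model of a dual-excitation fluorescent reporter protein that
#' interconverts between two states (reduced/oxidized for roGFP2-type redox
#' probes, protonated/deprotonated for pH probes). Channel intensities of a
#' colony are linear mixtures of the two pure-state intensities weighted by
#' the state fraction, scaled by colony brightness. The model is deliberately
#' minimal: it makes the oxidation-degree calculation an exact algebraic
#' inverse of the simulation, so parameter recovery is well posed.
#'
#' @param channel_a State-reporting excitation wavelength (nm), e.g. 380 or 454.
#' @param channel_b Reference excitation wavelength (nm), e.g. 470 or 580.
#' @param emission_nm Emission wavelength (nm).
#' @param I_a_red,I_b_red Per-unit-brightness channel intensities of the fully
#'   reduced (or protonated) state.
#' @param I_a_ox,I_b_ox Channel intensities of the fully oxidized (or
#'   deprotonated) state.
#' @param band_sigma_nm Gaussian excitation band width used when rendering
#'   synthetic excitation scans.
#' @return A `two_state_sensor` list.
#' @export
#' @examples
#' s <- sensor_mrx1_rogfp2()
#' s$I_a_red / s$I_b_red # fully reduced ratio, 0.53
two_state_sensor <- function(channel_a, channel_b, emission_nm,
                             I_a_red, I_b_red, I_a_ox, I_b_ox,
                             band_sigma_nm = 18) {
  vals <- c(I_a_red, I_b_red, I_a_ox, I_b_ox)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("All pure-state intensities must be positive.", class = "platesensor_sensor_error")
  }
  r_red <- I_a_red / I_b_red
  r_ox <- I_a_ox / I_b_ox
  if (!(r_red < r_ox)) {
    abort("Reduced-state ratio must be below oxidized-state ratio.",
      class = "platesensor_sensor_error"
    )
  }
  structure(
    list(
      channel_a = channel_a, channel_b = channel_b, emission_nm = emission_nm,
      I_a_red = I_a_red, I_b_red = I_b_red, I_a_ox = I_a_ox, I_b_ox = I_b_ox,
      band_sigma_nm = band_sigma_nm
    ),
    class = "two_state_sensor"
  )
}

#' Default Mrx1-roGFP2 redox sensor model
#'
#' Mycoredoxin-1 fused to redox-sensitive GFP2, read at 380/470 nm excitation
#' and 510 nm emission. The fully reduced biosensor ratio is 0.53 and the
#' fully oxidized ratio 1.4 (DTT- and NaOCl-treated colony controls); the
#' instrument factor I470_ox/I470_red defaults to 0.7.
#'
#' @return A `two_state_sensor`.
#' @export
sensor_mrx1_rogfp2 <- function() {
  two_state_sensor(
    channel_a = 380, channel_b = 470, emission_nm = 510,
    I_a_red = 0.53, I_b_red = 1.0,
    I_a_ox = 0.98, I_b_ox = 0.70
  )
}

#' Default mCherryEA pH sensor model
#'
#' pH-sensitive mCherry variant with excitation maxima at 454 and 580 nm,
#' emission 630 nm. The 454/580 ratio increases with internal pH (0.85 at
#' pH 7.0 to 1.35 at pH 8.5 in the plate-reader calibration); the two pure
#' states here bracket that span for scan rendering.
#'
#' @return A `two_state_sensor`.
#' @export
sensor_mcherry_ea <- function() {
  two_state_sensor(
    channel_a = 454, channel_b = 580, emission_nm = 630,
    I_a_red = 0.85, I_b_red = 1.0,
    I_a_ox = 1.35, I_b_ox = 1.0
  )
}

#' Mix the two sensor states at a given oxidation degree
#'
#' Noiseless channel intensities `I_ch = brightness * ((1 - oxd) * I_ch_red +
#' oxd * I_ch_ox)`.
#'
#' @param sensor A [two_state_sensor()].
#' @param oxd Oxidation degree (state fraction) in `[0, 1]`; vectorized.
#' @param brightness Positive per-colony scale factor; vectorized.
#' @return A tibble with columns `oxd`, `brightness`, `I_a`, `I_b`, `ratio`.
#' @export
sensor_intensities <- function(sensor, oxd, brightness = 1) {
  if (any(!is.finite(oxd)) || any(oxd < 0 | oxd > 1)) {
    abort("`oxd` must lie in [0, 1].", class = "platesensor_sensor_error")
  }
  if (any(brightness <= 0)) {
    abort("`brightness` must be positive.", class = "platesensor_sensor_error")
  }
  I_a <- brightness * ((1 - oxd) * sensor$I_a_red + oxd * sensor$I_a_ox)
  I_b <- brightness * ((1 - oxd) * sensor$I_b_red + oxd * sensor$I_b_ox)
  tibble(oxd = oxd, brightness = brightness, I_a = I_a, I_b = I_b, ratio = I_a / I_b)
}

#' Hill dose-response model for a transcription-factor-based biosensor
#'
#' Parameters of `F(c) = F0 + Fmax * c^n / (K^n + c^n)`: baseline reporter
#' fluorescence `F0`, induction span `Fmax`, half-saturation inducer
#' concentration `K` (same units as the dose, typically mM IPTG) and Hill
#' coefficient `n`. Empty-vector (reporter-free) strains are modeled with
#' `Fmax = 0`.
#'
#' @param F0 Baseline fluorescence (FLU), `>= 0`.
#' @param Fmax Induction span (FLU), `>= 0` (0 = flat, empty vector).
#' @param K Half-saturation dose, `> 0`.
#' @param n Hill coefficient, `> 0`.
#' @return A `tfb_model` list.
#' @export
tfb_model <- function(F0 = 4.96e3, Fmax = 1.93e5, K = 0.1, n = 1.5) {
  if (F0 < 0 || Fmax < 0 || K <= 0 || n <= 0) {
    abort("Require F0 >= 0, Fmax >= 0, K > 0, n > 0.", class = "platesensor_sensor_error")
  }
  structure(list(F0 = F0, Fmax = Fmax, K = K, n = n), class = "tfb_model")
}

#' Evaluate the Hill dose-response
#'
#' Dose 0 is handled exactly (the Hill term is 0), with no pseudo-dose offset.
#'
#' @param dose Inducer concentrations (`>= 0`); vectorized.
#' @param model A [tfb_model()] (or anything with `F0`, `Fmax`, `K`, `n`).
#' @return Numeric vector of noiseless responses (FLU).
#' @export
hill_response <- function(dose, model) {
  if (any(dose < 0)) abort("Doses must be >= 0.", class = "platesensor_sensor_error")
  term <- ifelse(dose == 0, 0, dose^model$n / (model$K^model$n + dose^model$n))
  model$F0 + model$Fmax * term
}
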