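#' Fully reduced / fully oxidized control intensities
#'
#' The four control intensities that normalize a roGFP2-type redox sensor:
#' channel intensities of a fully reduced (DTT-treated) and a fully oxidized
#' (NaOCl-treated) colony at 380 and 470 nm excitation. The reduced-control
#' ratio must lie below the oxidized-control ratio.
#'
#' @param I380_red,I470_red Intensities of the fully reduced control (FLU > 0).
#' @param I380_ox,I470_ox Intensities of the fully oxidized control (FLU > 0).
#' @return A `redox_controls` list.
#' @export
#' @examples
#' redox_controls(0.53, 1.0, 0.98, 0.70)
redox_controls <- function(I380_red, I470_red, I380_ox, I470_ox) {
  vals <- c(I380_red, I470_red, I380_ox, I470_ox)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("Control intensities must be positive and finite.",
      class = "platesensor_oxd_error"
    )
  }
  if (!(I380_red / I470_red < I380_ox / I470_ox)) {
    abort("Reduced-control ratio must be below oxidized-control ratio.",
      class = "platesensor_oxd_error"
    )
  }
  structure(
    list(
      I380_red = I380_red, I470_red = I470_red,
      I380_ox = I380_ox, I470_ox = I470_ox
    ),
    class = "redox_controls"
  )
}

#' Extract redox controls from an annotated plate
#'
#' Averages the 380/470 nm endpoint intensities of the wells annotated
#' `reduced_control` and `oxidized_control`.
#'
#' @param grid An annotated [plate_grid()].
#' @param channel_a,channel_b Excitation wavelengths (nm).
#' @return A [redox_controls()].
#' @export
plate_redox_controls <- function(grid, channel_a = 380, channel_b = 470) {
  mean_channel <- function(role, nm) {
    x <- dplyr::filter(
      as_tibble(grid), .data$role == !!role,
      .data$excitation_nm == nm, is.na(.data$time_s)
    )
    if (nrow(x) == 0) {
      abort(paste0("Plate has no ", nm, " nm reading for role '", role, "'."),
        class = "platesensor_oxd_error"
      )
    }
    mean(x$intensity)
  }
  redox_controls(
    I380_red = mean_channel("reduced_control", channel_a),
    I470_red = mean_channel("reduced_control", channel_b),
    I380_ox = mean_channel("oxidized_control", channel_a),
    I470_ox = mean_channel("oxidized_control", channel_b)
  )
}

#' Oxidation degree of a redox biosensor
#'
#' Fraction of sensor molecules in the oxidized state, computed by normalizing
#' the sample's 380/470 nm intensities to the fully reduced and fully oxidized
#' controls:
#'
#' \deqn{OxD = \frac{I380_s \cdot I470_{red} - I380_{red} \cdot I470_s}
#'   {I380_s \cdot I470_{red} - I380_s \cdot I470_{ox} + I380_{ox} \cdot I470_s
#'    - I380_{red} \cdot I470_s}}
#'
#' The value is returned unclamped together with an in-range flag: measurement
#' noise can push samples slightly outside `[0, 1]`, and preserving that is
#' useful for QC. OxD is invariant to a common rescaling of the sample's two
#' intensities (brightness independence).
#'
#' @param I380_sample,I470_sample Sample channel intensities (FLU > 0);
#'   vectorized.
#' @param controls A [redox_controls()].
#' @return A tibble `oxd, in_range`.
#' @export
#' @examples
#' ctl <- redox_controls(0.53, 1.0, 0.98, 0.70)
#' oxidation_degree(0.53, 1.0, ctl) # fully reduced sample: OxD 0
oxidation_degree <- function(I380_sample, I470_sample, controls) {
  if (!inherits(controls, "redox_controls")) {
    controls <- do.call(redox_controls, as.list(controls))
  }
  if (any(!is.finite(I380_sample)) || any(!is.finite(I470_sample)) ||
    any(I380_sample <= 0) || any(I470_sample <= 0)) {
    abort("Sample intensities must be positive and finite.",
      class = "platesensor_oxd_error"
    )
  }
  num <- I380_sample * controls$I470_red - controls$I380_red * I470_sample
  # denominator grouped to avoid catastrophic cancellation between products
  den <- I380_sample * (controls$I470_red - controls$I470_ox) +
    I470_sample * (controls$I380_ox - controls$I380_red)
  if (any(abs(den) < .Machine$double.eps * 100 * abs(I380_sample * controls$I470_red))) {
    abort("Degenerate controls: Eq. denominator vanishes.",
      class = "platesensor_oxd_error"
    )
  }
  oxd <- num / den
  tibble(oxd = oxd, in_range = oxd >= 0 & oxd <= 1)
}

#' Oxidation degree from biosensor ratios
#'
#' Ratio form of the oxidation degree, algebraically equivalent to
#' [oxidation_degree()] on any intensity tuple realizing the same ratios:
#' `OxD = (R - R_red) / ((R - R_red) + alpha * (R_ox - R))` where
#' `alpha = I470_ox / I470_red` is the instrument factor.
#'
#' @param R_sample Sample ratio(s) `I380/I470`; vectorized.
#' @param R_red,R_ox Fully reduced / fully oxidized control ratios
#'   (`R_red < R_ox`).
#' @param alpha Instrument factor `I470_ox / I470_red`, `> 0`.
#' @return A tibble `oxd, in_range`.
#' @export
oxd_from_ratios <- function(R_sample, R_red, R_ox, alpha) {
  if (!(R_red < R_ox)) {
    abort("Require R_red < R_ox.", class = "platesensor_oxd_error")
  }
  if (alpha <= 0) abort("`alpha` must be positive.", class = "platesensor_oxd_error")
  den <- (R_sample - R_red) + alpha * (R_ox - R_sample)
  if (any(abs(den) < .Machine$double.eps * 100)) {
    abort("Degenerate controls: denominator vanishes.", class = "platesensor_oxd_error")
  }
  oxd <- (R_sample - R_red) / den
  tibble(oxd = oxd, in_range = oxd >= 0 & oxd <= 1)
}

#' Per-well oxidation degrees of a plate
#'
#' Computes the biosensor ratio and Eq.-form oxidation degree for every sample
#' well, normalized either to explicit controls or to the plate's own control
#' wells.
#'
#' @param grid An annotated [plate_grid()].
#' @param controls A [redox_controls()]; default extracts them from the plate.
#' @param channel_a,channel_b Excitation wavelengths.
#' @param clamp Clamp OxD into `[0, 1]` (off by default; the in-range flag is
#'   reported either way).
#' @return A tibble `well, ratio, oxd, in_range` plus annotations.
#' @export
plate_oxd <- function(grid, controls = NULL, channel_a = 380, channel_b = 470,
                      clamp = FALSE) {
  if (is.null(controls)) controls <- plate_redox_controls(grid, channel_a, channel_b)
  ratios <- plate_ratios(grid, channel_a, channel_b)
  ratios <- dplyr::filter(ratios, is.na(.data$role) | .data$role == "sample")
  res <- oxidation_degree(ratios$I_num, ratios$I_den, controls)
  ratios$oxd <- if (clamp) pmin(pmax(res$oxd, 0), 1) else res$oxd
  ratios$in_range <- res$in_range
  ratios
}
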