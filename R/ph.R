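#' Fit a linear ratio-to-pH calibration
#'
#' Ordinary least-squares fit of `ratio = slope * pH + intercept` to in-colony
#' calibration standards (CTAB-permeabilized colonies equilibrated to buffers
#' of known pH). The sensor response is linear over the calibrated regime
#' (pH 7.0-8.5 for mCherryEA), so no titration-curve model is fitted.
#'
#' @param standards Data frame with columns `ph` and `ratio` (at least two
#'   distinct pH values).
#' @return A `ph_calibration` object with `slope`, `intercept`, `r_squared`,
#'   `domain` (observed pH span) and `n_points`; supports [tidy()], [glance()]
#'   and [autoplot()].
#' @export
#' @examples
#' fit_ph_calibration(data.frame(ph = c(7.0, 8.5), ratio = c(0.85, 1.35)))
fit_ph_calibration <- function(standards) {
  standards <- as_tibble(standards)
  if (!all(c("ph", "ratio") %in% names(standards))) {
    abort("`standards` needs columns `ph` and `ratio`.",
      class = "platesensor_calibration_error"
    )
  }
  standards <- dplyr::filter(standards, is.finite(.data$ph), is.finite(.data$ratio))
  if (length(unique(standards$ph)) < 2) {
    abort("Calibration needs >= 2 distinct pH values (singular fit).",
      class = "platesensor_calibration_error"
    )
  }
  fit <- lm(ratio ~ ph, data = standards)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((standards$ratio - mean(standards$ratio))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(
    list(
      slope = unname(coef(fit)["ph"]),
      intercept = unname(coef(fit)["(Intercept)"]),
      r_squared = r2,
      domain = range(standards$ph),
      n_points = nrow(standards),
      standards = standards
    ),
    class = "ph_calibration"
  )
}

#' @export
print.ph_calibration <- function(x, ...) {
  cat(
    "<ph_calibration> ratio = ", format(x$slope, digits = 4), " * pH + ",
    format(x$intercept, digits = 4), "  (r^2 = ", format(x$r_squared, digits = 4),
    ", n = ", x$n_points, ", pH ", x$domain[1], "-", x$domain[2], ")\n",
    sep = ""
  )
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ph_calibration <- function(x, ...) {
  tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @exportS3Method generics::glance
glance.ph_calibration <- function(x, ...) {
  tibble(
    r_squared = x$r_squared, n_points = x$n_points,
    ph_min = x$domain[1], ph_max = x$domain[2]
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.ph_calibration <- function(object, ...) {
  ggplot2::ggplot(object$standards, ggplot2::aes(x = .data$ph, y = .data$ratio)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      slope = object$slope, intercept = object$intercept,
      linetype = "dashed"
    ) +
    ggplot2::labs(x = "pH", y = "biosensor ratio") +
    ggplot2::theme_minimal()
}

#' Invert a calibration: ratio to pH
#'
#' Inverse prediction `pH = (ratio - intercept) / slope`, flagging ratios whose
#' predicted pH falls outside the calibrated domain.
#'
#' @param curve A [fit_ph_calibration()] result.
#' @param ratio Numeric vector of biosensor ratios.
#' @param warn_extrapolation Emit a warning when extrapolating.
#' @return A tibble `ratio, ph, extrapolated`.
#' @export
ratio_to_ph <- function(curve, ratio, warn_extrapolation = TRUE) {
  if (!inherits(curve, "ph_calibration")) {
    abort("`curve` must be a ph_calibration.", class = "platesensor_calibration_error")
  }
  if (curve$slope == 0) {
    abort("Zero calibration slope: pH is not identifiable.",
      class = "platesensor_calibration_error"
    )
  }
  ph <- (ratio - curve$intercept) / curve$slope
  tol <- sqrt(.Machine$double.eps) * diff(curve$domain)
  extrapolated <- ph < curve$domain[1] - tol | ph > curve$domain[2] + tol
  if (warn_extrapolation && any(extrapolated, na.rm = TRUE)) {
    warn(paste0(
      sum(extrapolated, na.rm = TRUE),
      " ratio(s) map outside the calibrated pH domain (extrapolation)."
    ))
  }
  tibble(ratio = ratio, ph = ph, extrapolated = extrapolated)
}

#' Per-well pH of a plate
#'
#' Computes per-colony biosensor ratios, fits (or reuses) a calibration from
#' the plate's `ph_standard` wells, and converts each sample colony's ratio to
#' internal pH. pH is computed per colony and then summarized, never from
#' averaged ratios.
#'
#' @param grid An annotated [plate_grid()].
#' @param curve Optional [fit_ph_calibration()]; default fits the plate's own
#'   standards (grouping replicate standards by their set pH).
#' @param numerator_nm,denominator_nm Ratio channels (454/580 default).
#' @return A tibble `well, ratio, ph, extrapolated` plus annotations.
#' @export
plate_ph <- function(grid, curve = NULL, numerator_nm = 454, denominator_nm = 580) {
  ratios <- plate_ratios(grid, numerator_nm, denominator_nm)
  if (is.null(curve)) {
    std <- dplyr::filter(ratios, .data$role == "ph_standard")
    if (nrow(std) == 0) {
      abort("Plate has no ph_standard wells and no calibration was supplied.",
        class = "platesensor_calibration_error"
      )
    }
    curve <- fit_ph_calibration(tibble(ph = std$role_value, ratio = std$ratio))
  }
  samples <- dplyr::filter(ratios, is.na(.data$role) | .data$role == "sample")
  pred <- ratio_to_ph(curve, samples$ratio, warn_extrapolation = FALSE)
  samples$ph <- pred$ph
  samples$extrapolated <- pred$extrapolated
  samples
}
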