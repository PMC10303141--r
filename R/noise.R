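#' Instrument/colony noise model for the synthetic generator
#'
#' Multiplicative Gaussian noise in two components plus an additive agar
#' background. `cv` is the per-colony coefficient of variation: one factor per
#' colony (per timepoint in kinetic mode), common to both excitation channels
#' of that colony. It models biomass/brightness variability, which cancels in
#' a ratiometric readout. `channel_cv` is the per-reading instrument noise,
#' drawn independently for every single read; it is what limits ratio
#' precision. Noisy intensities are truncated at 0.
#'
#' @param cv Common-mode (per-colony) coefficient of variation, `>= 0`.
#' @param channel_cv Per-reading coefficient of variation, `>= 0`.
#' @param background Additive agar background intensity (FLU); either a single
#'   value or a named vector keyed by excitation wavelength.
#' @param seed Integer seed; identical seed and configuration give identical
#'   output.
#' @return A `noise_model` list.
#' @export
#' @examples
#' noise_model(cv = 0.05)
#' noise_model(cv = 0, channel_cv = 0, background = c("380" = 500, "470" = 100))
noise_model <- function(cv = 0.05, channel_cv = 0.005, background = 0, seed = 0) {
  if (cv < 0 || channel_cv < 0 || any(background < 0)) {
    abort("cv, channel_cv and background must be >= 0.", class = "platesensor_noise_error")
  }
  structure(
    list(
      cv = cv, channel_cv = channel_cv,
      background = background, seed = as.integer(seed)
    ),
    class = "noise_model"
  )
}

noise_background <- function(noise, excitation_nm) {
  bg <- noise$background
  if (length(bg) == 1 && is.null(names(bg))) {
    return(rep(bg, length(excitation_nm)))
  }
  out <- unname(bg[as.character(excitation_nm)])
  out[is.na(out)] <- 0
  out
}

# Apply noise to a long reading table. `unit` groups rows that share one
# common-mode draw (typically well, or well x timepoint).
apply_noise <- function(readings, noise, unit) {
  stopifnot(length(unit) == nrow(readings))
  units <- unique(unit)
  common <- stats::rnorm(length(units), mean = 1, sd = noise$cv)
  common <- pmax(common, 0)
  f <- common[match(unit, units)]
  g <- pmax(stats::rnorm(nrow(readings), mean = 1, sd = noise$channel_cv), 0)
  bg <- noise_background(noise, readings$excitation_nm)
  readings$intensity <- pmax(readings$intensity * f * g + bg, 0)
  readings
}

# Evaluate code with a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
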