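#' Construct a kinetic ratio trace
#'
#' A kinetic trace is the per-timepoint biosensor ratio of one colony through
#' a treatment (reductant / oxidant / buffer drop applied at
#' `treatment_time_s`).
#'
#' @param times_s Strictly increasing timestamps (s).
#' @param ratios Biosensor ratios, same length.
#' @param treatment_time_s Treatment event time (s), within the trace span.
#' @param label Treatment label (e.g. `"DTT"`, `"NaOCl"`, `"PBS"`).
#' @return A `kinetic_trace` tibble (`time_s`, `ratio`) with attributes.
#' @export
kinetic_trace <- function(times_s, ratios, treatment_time_s, label = "treatment") {
  if (length(times_s) != length(ratios)) {
    abort("times and ratios must have equal length.", class = "platesensor_kinetics_error")
  }
  if (any(diff(times_s) <= 0)) {
    abort("Times must be strictly increasing.", class = "platesensor_kinetics_error")
  }
  structure(
    tibble(time_s = times_s, ratio = ratios),
    treatment_time_s = treatment_time_s,
    label = label,
    class = c("kinetic_trace", class(tibble()))
  )
}

#' Ratio trace from kinetic channel readings
#'
#' Pairs the two excitation channels at each timepoint and returns the
#' numerator/denominator ratio trace.
#'
#' @param readings Kinetic channel readings (e.g. from
#'   [simulate_kinetic_trace()] or a kinetic-mode plate CSV filtered to one
#'   well): columns `time_s`, `excitation_nm`, `intensity`.
#' @param numerator_nm,denominator_nm Excitation channels (380/470 default).
#' @param treatment_time_s Treatment time; defaults to the readings'
#'   `treatment_time_s` attribute.
#' @param label Trace label; defaults to the readings' attribute.
#' @return A [kinetic_trace()].
#' @export
trace_from_readings <- function(readings, numerator_nm = 380, denominator_nm = 470,
                                treatment_time_s = NULL, label = NULL) {
  treatment_time_s <- treatment_time_s %||% attr(readings, "treatment_time_s", exact = TRUE)
  label <- label %||% attr(readings, "label", exact = TRUE) %||% "treatment"
  if (is.null(treatment_time_s)) {
    abort("`treatment_time_s` is required.", class = "platesensor_kinetics_error")
  }
  wide <- tidyr::pivot_wider(
    dplyr::filter(
      as_tibble(readings),
      .data$excitation_nm %in% c(numerator_nm, denominator_nm)
    ),
    id_cols = "time_s", names_from = "excitation_nm", values_from = "intensity"
  )
  wide <- wide[order(wide$time_s), ]
  kinetic_trace(
    wide$time_s,
    wide[[as.character(numerator_nm)]] / wide[[as.character(denominator_nm)]],
    treatment_time_s = treatment_time_s, label = label
  )
}

#' Average replicate kinetic traces
#'
#' Pointwise mean of traces sharing a common time grid (replicate kinetic
#' experiments are averaged explicitly, never smoothed implicitly).
#'
#' @param traces List of [kinetic_trace()] objects on identical time grids.
#' @return A [kinetic_trace()].
#' @export
average_traces <- function(traces) {
  t0 <- traces[[1]]
  for (tr in traces[-1]) {
    if (!isTRUE(all.equal(tr$time_s, t0$time_s))) {
      abort("Traces must share a common time grid.", class = "platesensor_kinetics_error")
    }
  }
  ratios <- rowMeans(do.call(cbind, lapply(traces, function(tr) tr$ratio)))
  kinetic_trace(t0$time_s, ratios,
    treatment_time_s = attr(t0, "treatment_time_s", exact = TRUE),
    label = attr(t0, "label", exact = TRUE)
  )
}

#' Mean ratio over a time window
#'
#' Arithmetic mean of the ratios with timestamps in `[t_start, t_end)`.
#'
#' @param trace A [kinetic_trace()].
#' @param t_start,t_end Window bounds (s).
#' @return The mean ratio.
#' @export
steady_window_mean <- function(trace, t_start, t_end) {
  sel <- trace$time_s >= t_start & trace$time_s < t_end
  if (sum(sel) < 2) {
    abort("Window contains fewer than 2 points.", class = "platesensor_kinetics_error")
  }
  mean(trace$ratio[sel])
}

#' Time to reach a steady biosensor ratio after treatment
#'
#' The final-window mean is taken over the last 20% of post-treatment points.
#' The steady time is the earliest post-treatment timestamp from which every
#' subsequent ratio stays within `± band` of that mean for at least
#' `min_dwell_s`. By default the band is relative: a fraction of the response
#' amplitude `|final - pre|`, making the criterion scale-free across
#' treatments of different depth; `band_mode = "absolute"` interprets `band`
#' in ratio units. A trace that never stabilizes is flagged
#' (`steady = FALSE`), not raised.
#'
#' @param trace A [kinetic_trace()].
#' @param band Tolerance around the final mean (fraction of the response
#'   amplitude, or ratio units in absolute mode).
#' @param band_mode `"relative"` (default) or `"absolute"`.
#' @param min_dwell_s Minimum time the trace must remain in band (s).
#' @return A one-row tibble: `time_to_steady_s` (seconds after treatment),
#'   `steady`, `band_abs`, `final_mean`.
#' @export
time_to_steady <- function(trace, band = 0.02, band_mode = c("relative", "absolute"),
                           min_dwell_s = 120) {
  band_mode <- match.arg(band_mode)
  t0 <- attr(trace, "treatment_time_s", exact = TRUE)
  post <- trace[trace$time_s >= t0, ]
  pre <- trace[trace$time_s < t0, ]
  if (nrow(post) < 3 || nrow(pre) < 1) {
    abort("Need >= 3 post-treatment and >= 1 pre-treatment points.",
      class = "platesensor_kinetics_error"
    )
  }
  n_final <- max(2L, ceiling(0.2 * nrow(post)))
  final_mean <- mean(tail(post$ratio, n_final))
  band_abs <- if (band_mode == "relative") {
    amp <- abs(final_mean - mean(pre$ratio))
    if (amp == 0) band else band * amp
  } else {
    band
  }
  in_band <- abs(post$ratio - final_mean) <= band_abs
  # earliest index from which all subsequent points are in band
  ok_from <- rev(cumprod(rev(in_band))) == 1
  idx <- which(ok_from)
  t_end <- max(post$time_s)
  if (length(idx) > 0) {
    i <- idx[1]
    if (t_end - post$time_s[i] >= min_dwell_s) {
      return(tibble(
        time_to_steady_s = post$time_s[i] - t0, steady = TRUE,
        band_abs = band_abs, final_mean = final_mean
      ))
    }
  }
  tibble(
    time_to_steady_s = NA_real_, steady = FALSE,
    band_abs = band_abs, final_mean = final_mean
  )
}

#' Classify a treatment response from a kinetic trace
#'
#' Compares the mean pre-treatment ratio with the mean over the post-treatment
#' steady window (from [time_to_steady()] when resolvable, otherwise the last
#' 20% of post-treatment points). The colony is called `reduced` when the
#' ratio drops by at least `delta_threshold`, `oxidized` when it rises by at
#' least that much, and `unchanged` otherwise — a buffer-only drop causes at
#' most a transient excursion that has relaxed by the steady window.
#'
#' @param trace A [kinetic_trace()].
#' @param delta_threshold Minimum ratio change called a response (ratio
#'   units). The default 0.1 sits above buffer-drop transients and below the
#'   smallest genuine redox response of the Mrx1-roGFP2 system (about 0.14).
#' @param band,band_mode,min_dwell_s Passed to [time_to_steady()].
#' @return A one-row tibble: `label, pre_ratio, post_ratio, delta, call,
#'   time_to_steady_s, steady`.
#' @export
classify_redox_response <- function(trace, delta_threshold = 0.1,
                                    band = 0.02,
                                    band_mode = c("relative", "absolute"),
                                    min_dwell_s = 120) {
  band_mode <- match.arg(band_mode)
  t0 <- attr(trace, "treatment_time_s", exact = TRUE)
  pre <- trace[trace$time_s < t0, ]
  post <- trace[trace$time_s >= t0, ]
  if (nrow(pre) < 3 || nrow(post) < 3) {
    abort("Need >= 3 points before and after treatment.",
      class = "platesensor_kinetics_error"
    )
  }
  pre_ratio <- mean(pre$ratio)
  tts <- time_to_steady(trace, band = band, band_mode = band_mode, min_dwell_s = min_dwell_s)
  post_window <- if (tts$steady) {
    post[post$time_s - t0 >= tts$time_to_steady_s, ]
  } else {
    tail(post, max(2L, ceiling(0.2 * nrow(post))))
  }
  post_ratio <- mean(post_window$ratio)
  delta <- post_ratio - pre_ratio
  call <- if (delta <= -delta_threshold) {
    "reduced"
  } else if (delta >= delta_threshold) {
    "oxidized"
  } else {
    "unchanged"
  }
  tibble(
    label = attr(trace, "label", exact = TRUE) %||% NA_character_,
    pre_ratio = pre_ratio, post_ratio = post_ratio, delta = delta,
    call = call,
    time_to_steady_s = tts$time_to_steady_s, steady = tts$steady
  )
}
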