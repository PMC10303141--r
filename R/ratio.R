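#' Ratiometric biosensor signal from two channel readings
#'
#' Divides the state-reporting channel intensity by the reference channel
#' intensity. The wavelength metadata is mandatory and carried through, which
#' prevents silent swaps of the ratio orientation (mCherryEA is 454/580,
#' Mrx1-roGFP2 is 380/470 at 510 nm emission).
#'
#' @param numerator,denominator Channel readings: lists or one-row data frames
#'   with `excitation_nm`, `emission_nm`, `intensity`.
#' @return A one-row tibble: `value`, `numerator_exc_nm`, `denominator_exc_nm`,
#'   `emission_nm`.
#' @export
#' @examples
#' biosensor_ratio(
#'   list(excitation_nm = 454, emission_nm = 630, intensity = 5.8e6),
#'   list(excitation_nm = 580, emission_nm = 630, intensity = 6.8e6)
#' )
biosensor_ratio <- function(numerator, denominator) {
  num <- as.list(numerator)
  den <- as.list(denominator)
  for (r in list(num, den)) {
    if (!all(c("excitation_nm", "emission_nm", "intensity") %in% names(r))) {
      abort("Readings need excitation_nm, emission_nm and intensity.",
        class = "platesensor_ratio_error"
      )
    }
  }
  if (num$emission_nm != den$emission_nm) {
    abort("Emission wavelengths of the two channels must match.",
      class = "platesensor_ratio_error"
    )
  }
  if (!is.finite(num$intensity) || !is.finite(den$intensity) ||
    num$intensity <= 0 || den$intensity <= 0) {
    abort("Channel intensities must be positive for a ratio.",
      class = "platesensor_ratio_error"
    )
  }
  tibble(
    value = num$intensity / den$intensity,
    numerator_exc_nm = num$excitation_nm,
    denominator_exc_nm = den$excitation_nm,
    emission_nm = num$emission_nm
  )
}

#' Per-well biosensor ratios of a plate
#'
#' Computes the ratiometric signal for every well of a plate grid that has
#' endpoint readings at both excitation wavelengths.
#'
#' @param grid A [plate_grid()].
#' @param numerator_nm,denominator_nm Excitation wavelengths (numerator first:
#'   454/580 for mCherryEA, 380/470 for Mrx1-roGFP2).
#' @param emission_nm Optional emission filter; if `NULL` any shared emission
#'   is accepted.
#' @return A tibble `well, ratio, I_num, I_den` plus any layout annotation
#'   columns, in row-major well order.
#' @export
plate_ratios <- function(grid, numerator_nm, denominator_nm, emission_nm = NULL) {
  df <- dplyr::filter(
    as_tibble(grid), is.na(.data$time_s),
    .data$excitation_nm %in% c(numerator_nm, denominator_nm)
  )
  if (!is.null(emission_nm)) {
    df <- dplyr::filter(df, .data$emission_nm == !!emission_nm)
  }
  anno <- intersect(layout_columns, names(df))
  wide <- tidyr::pivot_wider(
    df,
    id_cols = dplyr::all_of(c("well", anno)),
    names_from = "excitation_nm", values_from = "intensity"
  )
  num_col <- as.character(numerator_nm)
  den_col <- as.character(denominator_nm)
  missing_wells <- character(0)
  for (col in c(num_col, den_col)) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  missing_wells <- wide$well[!is.finite(wide[[num_col]]) | !is.finite(wide[[den_col]])]
  if (length(missing_wells) > 0) {
    abort(
      paste0(
        "Missing channel reading(s) at ", numerator_nm, "/", denominator_nm,
        " nm for well(s): ", paste(head(missing_wells, 10), collapse = ", ")
      ),
      class = "platesensor_ratio_error"
    )
  }
  if (any(wide[[den_col]] <= 0)) {
    abort("Nonpositive denominator-channel intensity.", class = "platesensor_ratio_error")
  }
  out <- dplyr::transmute(wide,
    well = .data$well,
    ratio = .data[[num_col]] / .data[[den_col]],
    I_num = .data[[num_col]],
    I_den = .data[[den_col]],
    dplyr::across(dplyr::all_of(anno))
  )
  idx <- parse_well_label(out$well, plate_format(grid))
  out[order(idx$row, idx$col), ]
}

#' Locate excitation maxima in a scan
#'
#' Smooths the scan with a centered moving average and reports, per search
#' window, the wavelength of maximal smoothed intensity. Ties break toward the
#' lower wavelength. With `require_local_max = TRUE` the reported point must
#' be a strict local maximum of the smoothed scan (window-edge argmaxima are
#' rejected), which guards against monotone scans "peaking" at a window edge.
#'
#' @param scan An excitation scan: tibble with strictly increasing
#'   `excitation_nm` and `intensity` (at least 3 points).
#' @param windows List of `c(lambda_lo, lambda_hi)` search windows; default is
#'   the whole scan.
#' @param smooth_window_pts Odd moving-average width in points (`1` = none).
#' @param require_local_max Reject peaks that are not strict interior maxima.
#' @return A tibble `window_lo, window_hi, peak_nm, intensity` (raw intensity
#'   at the peak).
#' @export
find_excitation_peaks <- function(scan, windows = NULL, smooth_window_pts = 3,
                                  require_local_max = FALSE) {
  scan <- as_tibble(scan)
  if (nrow(scan) < 3 || any(diff(scan$excitation_nm) <= 0)) {
    abort("Scan needs >= 3 points with strictly increasing wavelengths.",
      class = "platesensor_scan_error"
    )
  }
  if (smooth_window_pts < 1 || smooth_window_pts %% 2 == 0) {
    abort("`smooth_window_pts` must be an odd integer >= 1.",
      class = "platesensor_scan_error"
    )
  }
  if (is.null(windows)) {
    windows <- list(range(scan$excitation_nm))
  }
  smoothed <- scan$intensity
  if (smooth_window_pts > 1) {
    k <- smooth_window_pts
    half <- (k - 1) / 2
    n <- length(smoothed)
    smoothed <- vapply(seq_len(n), function(i) {
      mean(scan$intensity[max(1, i - half):min(n, i + half)])
    }, numeric(1))
  }
  purrr::map_dfr(windows, function(w) {
    in_w <- which(scan$excitation_nm >= w[1] & scan$excitation_nm <= w[2])
    if (length(in_w) == 0) {
      abort("Empty peak-search window.", class = "platesensor_scan_error")
    }
    i_max <- in_w[which.max(smoothed[in_w])] # which.max breaks ties low
    if (require_local_max) {
      interior <- i_max > 1 && i_max < nrow(scan)
      strict <- interior &&
        smoothed[i_max] > smoothed[i_max - 1] && smoothed[i_max] > smoothed[i_max + 1]
      if (!strict) {
        abort("No interior local maximum in window.", class = "platesensor_scan_error")
      }
    }
    tibble(
      window_lo = w[1], window_hi = w[2],
      peak_nm = scan$excitation_nm[i_max],
      intensity = scan$intensity[i_max]
    )
  })
}
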