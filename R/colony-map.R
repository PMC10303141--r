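#' Per-colony metric map of a plate
#'
#' Computes a chosen per-colony metric (biosensor ratio, internal pH, or
#' oxidation degree) for every sample well and arranges it as a matrix in
#' plate orientation (A1 top-left), together with summary statistics over the
#' sample wells. The summary `range` is `max - min`, the span statistic used
#' to compare the precision of measurement methods (a narrower per-plate pH
#' span at equal mean indicates a more precise method).
#'
#' @param grid An annotated [plate_grid()].
#' @param metric One of `"ratio"`, `"ph"`, `"oxd"`.
#' @param numerator_nm,denominator_nm Ratio channels (defaults depend on
#'   metric: 454/580 for ratio/ph, 380/470 for oxd).
#' @param curve Optional [fit_ph_calibration()] for `metric = "ph"`.
#' @param controls Optional [redox_controls()] for `metric = "oxd"`.
#' @return A `colony_map`: list with `values` (numeric matrix, rows `A..`,
#'   columns `1..`), `data` (per-well tibble), `summary` (mean, sd, min, max,
#'   range, n) and `metric`. Supports [autoplot()].
#' @export
colony_map <- function(grid, metric = c("ratio", "ph", "oxd"),
                       numerator_nm = NULL, denominator_nm = NULL,
                       curve = NULL, controls = NULL) {
  metric <- match.arg(metric)
  fmt <- plate_format(grid)
  data <- switch(metric,
    ratio = {
      num <- numerator_nm %||% 454
      den <- denominator_nm %||% 580
      r <- plate_ratios(grid, num, den)
      r <- dplyr::filter(r, is.na(.data$role) | .data$role == "sample")
      dplyr::mutate(r, value = .data$ratio)
    },
    ph = {
      p <- plate_ph(grid,
        curve = curve,
        numerator_nm = numerator_nm %||% 454,
        denominator_nm = denominator_nm %||% 580
      )
      dplyr::mutate(p, value = .data$ph)
    },
    oxd = {
      o <- plate_oxd(grid,
        controls = controls,
        channel_a = numerator_nm %||% 380,
        channel_b = denominator_nm %||% 470
      )
      dplyr::mutate(o, value = .data$oxd)
    }
  )
  dims <- plate_dims(fmt)
  values <- matrix(NA_real_,
    nrow = dims[["nrow"]], ncol = dims[["ncol"]],
    dimnames = list(LETTERS[seq_len(dims[["nrow"]])], seq_len(dims[["ncol"]]))
  )
  idx <- parse_well_label(data$well, fmt)
  values[cbind(idx$row + 1L, idx$col + 1L)] <- data$value
  structure(
    list(
      values = values,
      data = data,
      summary = summarize_wells(data$value),
      metric = metric
    ),
    class = "colony_map"
  )
}

#' Summary statistics of per-colony values
#'
#' @param values Numeric vector (NA dropped).
#' @return A one-row tibble `mean, sd, min, max, range, n`; `range = max - min`.
#' @export
summarize_wells <- function(values) {
  values <- values[is.finite(values)]
  tibble(
    mean = mean(values), sd = sd(values),
    min = min(values), max = max(values),
    range = max(values) - min(values),
    n = length(values)
  )
}

#' @export
print.colony_map <- function(x, ...) {
  cat("<colony_map> metric:", x$metric, "\n")
  print(x$summary)
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.colony_map <- function(object, ...) {
  df <- object$data
  df$row_letter <- factor(substr(df$well, 1, 1), levels = rev(rownames(object$values)))
  df$col_num <- factor(as.integer(substring(df$well, 2)), levels = colnames(object$values))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col_num, y = .data$row_letter, fill = .data$value)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_viridis_c(name = object$metric) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
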