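plate_csv_columns <- c(
  "plate_id", "well", "excitation_nm", "emission_nm", "time_s", "intensity"
)

#' Read a canonical plate-reader CSV export
#'
#' The canonical export is long-format UTF-8 CSV with header columns
#' `plate_id, well, excitation_nm, emission_nm, time_s, intensity`; `time_s`
#' is empty for endpoint reads. Vendor-specific export dialects are out of
#' scope: convert to this schema first.
#'
#' @param path Path to the CSV file.
#' @param format Plate format (`96` or `384`); if `NULL`, inferred from the
#'   well labels (384 only when a label falls outside the 8 x 12 grid).
#' @return A [plate_grid()].
#' @export
read_plate_csv <- function(path, format = NULL) {
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  missing_cols <- setdiff(plate_csv_columns, trimws(gsub("\"", "", header)))
  if (length(missing_cols) > 0) {
    abort(
      paste0(
        "Plate CSV is missing header column(s): ",
        paste(missing_cols, collapse = ", ")
      ),
      class = "platesensor_validation_error"
    )
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      plate_id = readr::col_character(),
      well = readr::col_character(),
      excitation_nm = readr::col_double(),
      emission_nm = readr::col_double(),
      time_s = readr::col_double(),
      intensity = readr::col_double()
    ),
    progress = FALSE
  )
  missing_cols <- setdiff(plate_csv_columns, names(raw))
  if (length(missing_cols) > 0) {
    abort(
      paste0(
        "Plate CSV is missing header column(s): ",
        paste(missing_cols, collapse = ", ")
      ),
      class = "platesensor_validation_error"
    )
  }
  if (is.null(format)) {
    format <- tryCatch(
      {
        parse_well_label(unique(raw$well), 96)
        96L
      },
      error = function(e) 384L
    )
  }
  plate_grid(raw, format = format)
}

#' Write a plate grid as canonical CSV
#'
#' Writes only the reading columns (annotations travel in the layout file),
#' so `read_plate_csv(write_plate_csv(x))` round-trips the readings exactly.
#'
#' @param grid A `plate_grid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(grid, path) {
  readr::write_csv(grid[, plate_csv_columns], path, progress = FALSE)
  invisible(path)
}

#' Write a layout as CSV
#'
#' @param layout A layout tibble (see [apply_layout()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_layout_csv <- function(layout, path) {
  readr::write_csv(as_tibble(layout), path, progress = FALSE)
  invisible(path)
}
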