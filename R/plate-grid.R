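#' Construct a plate grid of colony readings
#'
#' A plate grid is a long-format tibble of fluorescence readings from arrayed
#' colonies (or wells), one row per reading, with the plate format carried as
#' an attribute. Readings are keyed by well, excitation wavelength, emission
#' wavelength, and (for kinetic mode) time; an endpoint reading has `NA`
#' `time_s`. Replicate reads of the same key are rejected: each colony is read
#' once per channel in endpoint mode, so a duplicate key indicates a corrupted
#' export rather than a replicate to be averaged.
#'
#' @param readings A data frame with columns `well`, `excitation_nm`,
#'   `emission_nm`, `time_s`, `intensity`. A `plate_id` column is optional if
#'   `plate_id` is given.
#' @param plate_id Plate identifier; defaults to the one found in `readings`.
#' @param format Plate format, `96` or `384`.
#' @return A `plate_grid` tibble.
#' @export
#' @examples
#' plate_grid(
#'   tibble::tibble(
#'     well = "A1", excitation_nm = c(380, 470), emission_nm = 510,
#'     time_s = NA_real_, intensity = c(1200, 1500)
#'   ),
#'   plate_id = "demo", format = 96
#' )
plate_grid <- function(readings, plate_id = NULL, format = 96) {
  format <- check_plate_format(format)
  readings <- as_tibble(readings)
  needed <- c("well", "excitation_nm", "emission_nm", "intensity")
  missing_cols <- setdiff(needed, names(readings))
  if (length(missing_cols) > 0) {
    abort(
      paste0("Missing reading column(s): ", paste(missing_cols, collapse = ", ")),
      class = "platesensor_validation_error"
    )
  }
  if (!"time_s" %in% names(readings)) readings$time_s <- NA_real_
  if (is.null(plate_id)) {
    ids <- unique(readings$plate_id)
    if (length(ids) != 1) {
      abort("`readings` must contain exactly one plate_id (or pass `plate_id`).",
        class = "platesensor_validation_error"
      )
    }
    plate_id <- ids
  }
  readings$plate_id <- as.character(plate_id)

  parse_well_label(unique(readings$well), format) # validates addresses

  bad_int <- which(!is.finite(readings$intensity) | readings$intensity < 0)
  if (length(bad_int) > 0) {
    abort(
      paste0(
        "Intensities must be finite and >= 0; offending row(s): ",
        paste(head(bad_int, 10), collapse = ", ")
      ),
      class = "platesensor_validation_error"
    )
  }
  if (any(readings$excitation_nm <= 0 | readings$emission_nm <= 0)) {
    abort("Wavelengths must be positive.", class = "platesensor_validation_error")
  }
  key <- paste(readings$well, readings$excitation_nm, readings$emission_nm,
    ifelse(is.na(readings$time_s), "endpoint", readings$time_s),
    sep = "|"
  )
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    abort(
      paste0(
        "Duplicate reading key (well, excitation, emission, time) at row(s): ",
        paste(head(dup, 10), collapse = ", ")
      ),
      class = "platesensor_validation_error"
    )
  }

  front <- c("plate_id", "well", "excitation_nm", "emission_nm", "time_s", "intensity")
  readings <- readings[, c(front, setdiff(names(readings), front))]
  structure(readings,
    plate_format = format,
    class = c("plate_grid", class(as_tibble(readings)))
  )
}

#' Plate format of a plate grid
#'
#' @param x A `plate_grid` (or any tibble carrying a `plate_format` attribute).
#' @return 96 or 384.
#' @export
plate_format <- function(x) {
  fmt <- attr(x, "plate_format", exact = TRUE)
  if (is.null(fmt)) {
    # infer from labels: anything beyond the 96 grid means 384
    fmt <- tryCatch(
      {
        parse_well_label(unique(x$well), 96)
        96L
      },
      error = function(e) 384L
    )
  }
  fmt
}

#' @export
print.plate_grid <- function(x, ...) {
  cat(
    "<plate_grid> plate ", unique(x$plate_id), " (", plate_format(x), "-format), ",
    length(unique(x$well)), " wells, ", nrow(x), " readings\n",
    sep = ""
  )
  NextMethod()
}

# Keep class/attributes through dplyr verbs.
#' @exportS3Method dplyr::dplyr_reconstruct
dplyr_reconstruct.plate_grid <- function(data, template) {
  out <- NextMethod()
  attr(out, "plate_format") <- attr(template, "plate_format", exact = TRUE)
  class(out) <- class(template)
  out
}

#' @export
`[.plate_grid` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "plate_format") <- attr(x, "plate_format", exact = TRUE)
    class(out) <- class(x)
  }
  out
}

layout_columns <- c(
  "strain", "condition", "dose", "role", "role_value",
  "size_px", "perimeter_px", "od600"
)

plate_roles <- c("sample", "blank", "reduced_control", "oxidized_control", "ph_standard")

#' Annotate a plate grid with a layout
#'
#' Joins strain/condition/dose/role annotations onto the readings of a plate.
#' Wells present in the readings but absent from the layout are annotated as
#' `role = "blank"`. Layout wells outside the plate format are an error.
#'
#' @param grid A `plate_grid`.
#' @param layout A data frame with a `well` column and any of `strain`,
#'   `condition`, `dose`, `role`, `role_value`, `size_px`, `perimeter_px`,
#'   `od600` — or a path to a CSV/TSV file with those columns.
#' @return The annotated `plate_grid`.
#' @export
apply_layout <- function(grid, layout) {
  fmt <- plate_format(grid)
  layout <- read_layout(layout)
  parse_well_label(unique(layout$well), fmt)
  if (anyDuplicated(layout$well)) {
    abort("Layout has duplicate wells.", class = "platesensor_validation_error")
  }
  for (col in layout_columns) {
    if (!col %in% names(layout)) {
      layout[[col]] <- if (col %in% c("strain", "condition", "role")) NA_character_ else NA_real_
    }
  }
  layout$role <- ifelse(is.na(layout$role), "sample", layout$role)
  bad_role <- setdiff(unique(layout$role), plate_roles)
  if (length(bad_role) > 0) {
    abort(paste0("Unknown role(s): ", paste(bad_role, collapse = ", ")),
      class = "platesensor_validation_error"
    )
  }
  if (any(layout$role == "ph_standard" & !is.finite(layout$role_value))) {
    abort("ph_standard wells require a numeric role_value (the standard pH).",
      class = "platesensor_validation_error"
    )
  }
  out <- grid
  out <- dplyr::select(out, -dplyr::any_of(layout_columns))
  out <- dplyr::left_join(out, layout[, c("well", layout_columns)], by = "well")
  out$role <- ifelse(is.na(out$role), "blank", out$role)
  out
}

#' Read a plate layout file
#'
#' @param layout A data frame or path to a CSV/TSV layout file (columns `well`
#'   plus annotations; see [apply_layout()]).
#' @return A tibble.
#' @export
read_layout <- function(layout) {
  if (is.character(layout) && length(layout) == 1) {
    delim <- if (grepl("\\.tsv$", layout, ignore.case = TRUE)) "\t" else ","
    layout <- readr::read_delim(layout,
      delim = delim, show_col_types = FALSE,
      progress = FALSE
    )
  }
  layout <- as_tibble(layout)
  if (!"well" %in% names(layout)) {
    abort("Layout must have a `well` column.", class = "platesensor_validation_error")
  }
  layout
}

#' Select colony records by annotation
#'
#' Filters the readings of annotated wells by strain, condition, role and/or
#' dose, returned in stable row-major (A1, A2, ...) well order.
#'
#' @param grid An annotated `plate_grid`.
#' @param strain,condition,role Optional character filters (exact match).
#' @param dose Optional numeric filter (exact match).
#' @return A tibble of the selected readings (possibly empty).
#' @export
select_group <- function(grid, strain = NULL, condition = NULL, role = NULL, dose = NULL) {
  out <- grid
  if (!is.null(strain)) out <- dplyr::filter(out, .data$strain %in% !!strain)
  if (!is.null(condition)) out <- dplyr::filter(out, .data$condition %in% !!condition)
  if (!is.null(role)) out <- dplyr::filter(out, .data$role %in% !!role)
  if (!is.null(dose)) out <- dplyr::filter(out, .data$dose %in% !!dose)
  idx <- parse_well_label(out$well, plate_format(grid))
  out[order(idx$row, idx$col, out$excitation_nm, out$emission_nm, out$time_s), ]
}
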