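#' Plate format dimensions
#'
#' Row/column dimensions of the supported ANSI/SLAS plate formats. Arrayed
#' colonies on rectangular (OmniTray-style) agar plates are pinned on the same
#' footprint, so colony positions map one-to-one onto well addresses.
#'
#' @param format Plate format, `96` or `384`.
#' @return A named integer vector with elements `nrow` and `ncol`.
#' @export
#' @examples
#' plate_dims(96)
plate_dims <- function(format) {
  format <- check_plate_format(format)
  if (format == 96L) c(nrow = 8L, ncol = 12L) else c(nrow = 16L, ncol = 24L)
}

check_plate_format <- function(format) {
  if (length(format) != 1 || !format %in% c(96, 384)) {
    abort("`format` must be 96 or 384.", class = "platesensor_format_error")
  }
  as.integer(format)
}

#' Parse well labels into grid indices
#'
#' Converts `"A1"`-style labels to 0-based row/column indices for the given
#' plate format. Labels are the user-facing convention (1-based, letter rows);
#' indices are the internal convention used for array math.
#'
#' @param label Character vector of well labels such as `"A1"` or `"P24"`.
#' @param format Plate format, `96` (8 x 12) or `384` (16 x 24).
#' @return A tibble with columns `label`, `row`, `col` (0-based integers).
#' @export
#' @examples
#' parse_well_label(c("A1", "H12"), 96)
parse_well_label <- function(label, format = 96) {
  format <- check_plate_format(format)
  dims <- plate_dims(format)
  if (!is.character(label)) {
    abort("`label` must be a character vector.", class = "platesensor_address_error")
  }
  ok <- grepl("^[A-P][0-9]{1,2}$", label)
  if (any(!ok)) {
    abort(
      paste0("Malformed well label(s): ", paste(unique(label[!ok]), collapse = ", ")),
      class = "platesensor_address_error"
    )
  }
  row <- match(substr(label, 1, 1), LETTERS) - 1L
  col <- as.integer(substring(label, 2)) - 1L
  bad <- row >= dims[["nrow"]] | col < 0L | col >= dims[["ncol"]]
  if (any(bad)) {
    abort(
      paste0(
        "Well label(s) out of range for ", format, "-format plate: ",
        paste(unique(label[bad]), collapse = ", ")
      ),
      class = "platesensor_address_error"
    )
  }
  tibble(label = label, row = row, col = col)
}

#' Format grid indices as well labels
#'
#' Inverse of [parse_well_label()].
#'
#' @param row,col 0-based integer indices.
#' @param format Plate format, `96` or `384`.
#' @return Character vector of labels.
#' @export
format_well_label <- function(row, col, format = 96) {
  format <- check_plate_format(format)
  dims <- plate_dims(format)
  if (any(row < 0 | row >= dims[["nrow"]] | col < 0 | col >= dims[["ncol"]])) {
    abort("row/col indices out of range for format.", class = "platesensor_address_error")
  }
  paste0(LETTERS[row + 1L], col + 1L)
}

#' All well labels of a plate format in row-major order
#'
#' @param format Plate format, `96` or `384`.
#' @return Character vector of length `format`.
#' @export
well_labels <- function(format = 96) {
  dims <- plate_dims(format)
  grid <- expand.grid(col = seq_len(dims[["ncol"]]) - 1L, row = seq_len(dims[["nrow"]]) - 1L)
  format_well_label(grid$row, grid$col, format)
}
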