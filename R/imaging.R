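#' Construct a colony image
#'
#' A grayscale plate image of arrayed colonies: a numeric matrix of
#' nonnegative pixel intensities whose aspect ratio matches the declared plate
#' format (within 10%), with well centers assumed on the regular ANSI/SLAS
#' pitch grid scaled to the image extent.
#'
#' @param pixels Numeric matrix (rows = image rows).
#' @param format Plate format, `96` or `384`.
#' @param px_per_mm Optional physical scale.
#' @return A `colony_image` (matrix with attributes).
#' @export
colony_image <- function(pixels, format = 96, px_per_mm = NULL) {
  format <- check_plate_format(format)
  if (!is.matrix(pixels) || any(!is.finite(pixels)) || any(pixels < 0)) {
    abort("`pixels` must be a finite nonnegative matrix.", class = "platesensor_image_error")
  }
  dims <- plate_dims(format)
  aspect <- (nrow(pixels) / ncol(pixels)) / (dims[["nrow"]] / dims[["ncol"]])
  if (abs(aspect - 1) > 0.1) {
    abort("Image aspect ratio inconsistent with plate format.",
      class = "platesensor_image_error"
    )
  }
  structure(pixels,
    plate_format = format, px_per_mm = px_per_mm,
    class = c("colony_image", "matrix", "array")
  )
}

# Well centers in pixel coordinates (row, col), row-major well order.
well_centers_px <- function(format, n_row_px, n_col_px) {
  dims <- plate_dims(format)
  pitch_r <- n_row_px / dims[["nrow"]]
  pitch_c <- n_col_px / dims[["ncol"]]
  grid <- expand.grid(col = seq_len(dims[["ncol"]]) - 1L, row = seq_len(dims[["nrow"]]) - 1L)
  tibble(
    well = format_well_label(grid$row, grid$col, format),
    center_row = (grid$row + 0.5) * pitch_r,
    center_col = (grid$col + 0.5) * pitch_c,
    pitch = min(pitch_r, pitch_c)
  )
}

#' Simulate a plate image of arrayed colonies
#'
#' Renders colonies as uniform disks centered on the well grid of an
#' ANSI/SLAS-proportioned image, over a uniform agar background, with additive
#' Gaussian pixel noise.
#'
#' @param layout Tibble with columns `well`, `radius_px` (0 = missing colony)
#'   and optionally `intensity` (default 1000).
#' @param format Plate format.
#' @param image_width_px Image width; height follows the format aspect ratio.
#' @param background Background pixel intensity.
#' @param noise_sd Gaussian pixel noise sd.
#' @param seed RNG seed.
#' @param offset_px Optional tibble `well, d_row, d_col` of colony-center
#'   offsets (for testing grid alignment).
#' @return A [colony_image()].
#' @export
simulate_colony_image <- function(layout, format = 96, image_width_px = 480,
                                  background = 100, noise_sd = 0, seed = 0,
                                  offset_px = NULL) {
  format <- check_plate_format(format)
  layout <- as_tibble(layout)
  if (!"intensity" %in% names(layout)) layout$intensity <- 1000
  dims <- plate_dims(format)
  h <- as.integer(round(image_width_px * dims[["nrow"]] / dims[["ncol"]]))
  img <- matrix(background, nrow = h, ncol = image_width_px)
  centers <- well_centers_px(format, h, image_width_px)
  lay <- dplyr::left_join(layout, centers, by = "well")
  if (any(lay$radius_px > lay$pitch / 2)) {
    abort("Colony radius exceeds half the well pitch.", class = "platesensor_image_error")
  }
  if (!is.null(offset_px)) {
    lay <- dplyr::left_join(lay, as_tibble(offset_px), by = "well")
    lay$d_row[is.na(lay$d_row)] <- 0
    lay$d_col[is.na(lay$d_col)] <- 0
    lay$center_row <- lay$center_row + lay$d_row
    lay$center_col <- lay$center_col + lay$d_col
  }
  rows <- matrix(seq_len(h), nrow = h, ncol = image_width_px)
  cols <- matrix(seq_len(image_width_px), nrow = h, ncol = image_width_px, byrow = TRUE)
  for (i in seq_len(nrow(lay))) {
    if (lay$radius_px[i] <= 0) next
    d2 <- (rows - lay$center_row[i])^2 + (cols - lay$center_col[i])^2
    img[d2 <= lay$radius_px[i]^2] <- lay$intensity[i]
  }
  if (noise_sd > 0) {
    img <- with_seed(seed, img + matrix(rnorm(length(img), 0, noise_sd), nrow = h))
    img <- pmax(img, 0)
  }
  colony_image(img, format = format)
}

# Boundary-edge-count perimeter of a logical mask: the number of pixel edges
# between foreground and background/outside (4-connectivity boundary length).
# Overestimates the Euclidean circumference of a digital disk by ~4/pi.
mask_perimeter <- function(mask) {
  if (!any(mask)) {
    abort("Empty mask has no perimeter.", class = "platesensor_image_error")
  }
  m <- matrix(as.integer(mask), nrow = nrow(mask))
  padded <- matrix(0L, nrow = nrow(m) + 2, ncol = ncol(m) + 2)
  padded[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  up <- padded[1:(nrow(padded) - 2), 2:(ncol(padded) - 1)]
  down <- padded[3:nrow(padded), 2:(ncol(padded) - 1)]
  left <- padded[2:(nrow(padded) - 1), 1:(ncol(padded) - 2)]
  right <- padded[2:(nrow(padded) - 1), 3:ncol(padded)]
  sum(m * ((1 - up) + (1 - down) + (1 - left) + (1 - right)))
}

#' Perimeter of a colony region mask
#'
#' Boundary-edge count: the number of exposed pixel edges of the foreground
#' region (4-connectivity boundary length). This estimator is transparent and
#' exactly testable (a 1x1 pixel has perimeter 4, an n x n square 4n); on
#' digital disks it overestimates the Euclidean circumference `2*pi*r` by a
#' documented factor of about `4/pi`.
#'
#' @param mask Logical (or 0/1) matrix, `TRUE` = colony.
#' @return Perimeter in pixel edges.
#' @export
region_perimeter <- function(mask) {
  mask_perimeter(mask > 0)
}

#' Segment arrayed colonies from a plate image
#'
#' Global Otsu threshold, 8-connected components, and nearest-well-center
#' assignment on the format's pitch grid. At most one region is kept per well
#' (the largest); wells without a component are reported absent. Foreground
#' components whose centroid is farther than half the well pitch from every
#' well center are unassignable; when they carry more than 30% of the
#' foreground area the grid is considered misaligned and an error is raised.
#'
#' @param image A [colony_image()] (or plain matrix plus `format`).
#' @param format Plate format if `image` is a plain matrix.
#' @param threshold `"otsu"` or a numeric global threshold.
#' @return A tibble: `well, present, area_px, perimeter_px, centroid_row,
#'   centroid_col`, one row per well in row-major order.
#' @export
segment_colony_grid <- function(image, format = NULL, threshold = "otsu") {
  format <- format %||% attr(image, "plate_format", exact = TRUE) %||% 96
  img <- unclass(image)
  attr(img, "plate_format") <- NULL
  attr(img, "px_per_mm") <- NULL
  rng <- range(img)
  if (identical(threshold, "otsu")) {
    if (rng[1] == rng[2]) {
      th <- rng[2] # flat image: nothing above threshold
    } else {
      norm <- (img - rng[1]) / (rng[2] - rng[1])
      th_norm <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
      th <- rng[1] + th_norm * (rng[2] - rng[1])
    }
  } else {
    th <- threshold
  }
  mask <- img > th
  centers <- well_centers_px(format, nrow(img), ncol(img))
  out <- centers[, c("well", "center_row", "center_col")]
  out$present <- FALSE
  out$area_px <- 0
  out$perimeter_px <- 0
  out$centroid_row <- NA_real_
  out$centroid_col <- NA_real_
  if (any(mask)) {
    labels <- EBImage::bwlabel(EBImage::Image(mask * 1))
    lab <- as.integer(round(as.numeric(EBImage::imageData(labels))))
    lab <- matrix(lab, nrow = nrow(img))
    comp_ids <- sort(unique(lab[lab > 0]))
    rows <- row(lab)
    cols <- col(lab)
    comp <- tibble(
      id = comp_ids,
      area = as.numeric(tapply(lab[lab > 0], lab[lab > 0], length)),
      c_row = as.numeric(tapply(rows[lab > 0], lab[lab > 0], mean)),
      c_col = as.numeric(tapply(cols[lab > 0], lab[lab > 0], mean))
    )
    d2 <- outer(comp$c_row, centers$center_row, `-`)^2 +
      outer(comp$c_col, centers$center_col, `-`)^2
    nearest <- apply(d2, 1, which.min)
    nearest_d <- sqrt(d2[cbind(seq_len(nrow(comp)), nearest)])
    assignable <- nearest_d <= centers$pitch[1] / 2
    if (sum(comp$area[!assignable]) > 0.3 * sum(comp$area)) {
      abort("More than 30% of foreground is unassignable to wells: grid misalignment.",
        class = "platesensor_image_error"
      )
    }
    comp$well <- ifelse(assignable, centers$well[nearest], NA_character_)
    comp <- comp[!is.na(comp$well), ]
    comp <- comp[order(comp$well, -comp$area), ]
    comp <- comp[!duplicated(comp$well), ]
    for (i in seq_len(nrow(comp))) {
      j <- match(comp$well[i], out$well)
      out$present[j] <- TRUE
      out$area_px[j] <- comp$area[i]
      out$perimeter_px[j] <- mask_perimeter(lab == comp$id[i])
      out$centroid_row[j] <- comp$c_row[i]
      out$centroid_col[j] <- comp$c_col[i]
    }
  }
  out[, c("well", "present", "area_px", "perimeter_px", "centroid_row", "centroid_col")]
}

#' Relative colony sizes of a dilution series
#'
#' Colony areas expressed as percentages of the undiluted (step 0) colony of
#' the same strain, aggregated as mean ± sd per strain and step.
#'
#' @param regions Tibble with columns `strain`, `step` (0 = undiluted),
#'   `area_px`, and optionally `replicate`.
#' @return A tibble `strain, step, mean_pct, sd_pct, n`.
#' @export
relative_sizes <- function(regions) {
  regions <- as_tibble(regions)
  if (!"replicate" %in% names(regions)) regions$replicate <- 1L
  ref <- dplyr::filter(regions, .data$step == 0)
  if (nrow(ref) == 0 || any(ref$area_px <= 0)) {
    abort("Each strain needs a step-0 colony with positive area.",
      class = "platesensor_image_error"
    )
  }
  ref <- dplyr::summarise(dplyr::group_by(ref, .data$strain, .data$replicate),
    area0 = .data$area_px[1], .groups = "drop"
  )
  joined <- dplyr::inner_join(regions, ref, by = c("strain", "replicate"))
  joined$pct <- 100 * joined$area_px / joined$area0
  dplyr::summarise(
    dplyr::group_by(joined, .data$strain, .data$step),
    mean_pct = mean(.data$pct), sd_pct = sd(.data$pct), n = dplyr::n(),
    .groups = "drop"
  )
}

#' Colony centering offset from an in-well absorbance scan
#'
#' The plate reader can raster a 30 x 30 absorbance scan across each well
#' position; a pinned colony should sit centered in its scan. The offset is
#' the background-subtracted intensity-weighted centroid minus the scan
#' center, in scan units. Background is estimated as the median scan value
#' (the colony occupies a minority of the scanned area); a scan that is
#' (near-)uniform after subtraction carries no colony.
#'
#' @param well_scan Numeric matrix (default expectation 30 x 30) of
#'   nonnegative absorbances.
#' @param centered_tol Offset magnitude (scan units) still called centered.
#' @return A one-row tibble: `d_row, d_col, centered, present`.
#' @export
centering_offset <- function(well_scan, centered_tol = 3) {
  if (!is.matrix(well_scan) || any(!is.finite(well_scan)) || any(well_scan < 0)) {
    abort("`well_scan` must be a finite nonnegative matrix.",
      class = "platesensor_image_error"
    )
  }
  bg <- median(well_scan)
  w <- pmax(well_scan - bg, 0)
  total <- sum(w)
  if (total <= .Machine$double.eps * length(w) * max(well_scan, 1)) {
    return(tibble(d_row = NA_real_, d_col = NA_real_, centered = FALSE, present = FALSE))
  }
  center_r <- (nrow(well_scan) + 1) / 2
  center_c <- (ncol(well_scan) + 1) / 2
  d_row <- sum(row(w) * w) / total - center_r
  d_col <- sum(col(w) * w) / total - center_c
  tibble(
    d_row = d_row, d_col = d_col,
    centered = abs(d_row) <= centered_tol && abs(d_col) <= centered_tol,
    present = TRUE
  )
}
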