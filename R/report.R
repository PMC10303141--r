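#' Write a plate-orientation heat map
#'
#' The CSV matrix (rows `A..`, columns `1..`) is the source of truth; the
#' rendered image is presentational. Absent wells are empty CSV cells.
#'
#' @param values Numeric matrix in plate orientation (as in
#'   [colony_map()]`$values`).
#' @param csv_path Output CSV path.
#' @param image_path Optional output image path (PNG via ggplot2).
#' @param name Fill-scale label.
#' @return The ggplot object, invisibly.
#' @export
render_heatmap <- function(values, csv_path, image_path = NULL, name = "value") {
  df <- as_tibble(values, rownames = "row")
  readr::write_csv(df, csv_path, progress = FALSE, na = "")
  long <- tidyr::pivot_longer(df, -"row", names_to = "col", values_to = "value")
  long$col <- factor(long$col, levels = colnames(values))
  long$row <- factor(long$row, levels = rev(rownames(values)))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_viridis_c(name = name, na.value = "grey50") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(image_path)) {
    ggplot2::ggsave(image_path, p, width = 7, height = 5, dpi = 150)
  }
  invisible(p)
}

#' Read a heat-map CSV back into a matrix
#'
#' @param csv_path Path written by [render_heatmap()].
#' @return Numeric matrix with row/column dimnames.
#' @export
read_heatmap_csv <- function(csv_path) {
  df <- readr::read_csv(csv_path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$row
  m
}

cli_defaults <- list(
  numerator_nm = 454, denominator_nm = 580,
  redox_numerator_nm = 380, redox_denominator_nm = 470,
  delta_threshold = 0.1, band = 0.02, band_mode = "relative",
  min_dwell_s = 120, centered_tol = 3, significance_alpha = 0.05,
  noise_cv = 0.05, noise_channel_cv = 0.005, seed = 0
)

write_manifest <- function(out_dir, subcommand, opts, inputs = character(0)) {
  checksums <- if (length(inputs) > 0) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(
    tool = "platesensor",
    version = as.character(utils::packageVersion("platesensor")),
    subcommand = subcommand,
    config = opts,
    defaults = cli_defaults,
    input_md5 = checksums
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
}

parse_cli_args <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) {
      abort(paste0("Unexpected argument: ", a), class = "platesensor_usage_error")
    }
    key <- gsub("-", "_", substring(a, 3))
    if (i == length(args) || startsWith(args[[i + 1]], "--")) {
      opts[[key]] <- TRUE
      i <- i + 1
    } else {
      val <- args[[i + 1]]
      num <- suppressWarnings(as.numeric(val))
      opts[[key]] <- if (!is.na(num)) num else val
      i <- i + 2
    }
  }
  opts
}

cli_subcommands <- c(
  "simulate", "ratio", "calibrate-ph", "ph-map", "oxd",
  "dose-response", "kinetics", "sizes", "report"
)

#' Command-line entry point
#'
#' Dispatches the package's analysis stages as subcommands over canonical
#' plate/layout CSV files, writing CSV/JSON artifacts plus a machine-readable
#' run manifest (configuration echo including all defaults, package version,
#' seed, input checksums) into `--out`. Designed to be called from the thin
#' wrapper script in `inst/cli/platesensor.R`, and callable in-process for
#' testing.
#'
#' Subcommands: `simulate` (`--mode redox|ph|tfb|dilution --seed N --out DIR`),
#' `ratio`, `calibrate-ph`, `ph-map`, `oxd`, `dose-response`
#' (`--plate F --layout F --out DIR` ...), `kinetics`
#' (`--plate F --treatment-time T --num 380 --den 470 --out DIR`),
#' `sizes` (`--regions F --out DIR`), `report`
#' (`--plate F --layout F --reference STRAIN --num .. --den .. --out DIR`).
#'
#' @param args Character vector of command-line arguments.
#' @return Exit code, invisibly: 0 success, 2 validation error, 64 usage
#'   error.
#' @export
plate_cli <- function(args) {
  if (length(args) == 0 || !args[[1]] %in% cli_subcommands) {
    message(
      "usage: platesensor <subcommand> [--options]\n",
      "subcommands: ", paste(cli_subcommands, collapse = ", ")
    )
    return(invisible(64L))
  }
  sub <- args[[1]]
  code <- tryCatch(
    {
      opts <- parse_cli_args(args[-1])
      cli_dispatch(sub, opts)
      0L
    },
    platesensor_usage_error = function(e) {
      message("usage error: ", conditionMessage(e))
      64L
    },
    error = function(e) {
      message("error: ", conditionMessage(e))
      2L
    }
  )
  invisible(code)
}

cli_require <- function(opts, keys) {
  missing <- setdiff(keys, names(opts))
  if (length(missing) > 0) {
    abort(paste0("Missing required option(s): --", paste(missing, collapse = ", --")),
      class = "platesensor_usage_error"
    )
  }
}

cli_out_dir <- function(opts) {
  out <- opts$out %||% "."
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  out
}

cli_load_plate <- function(opts) {
  cli_require(opts, "plate")
  grid <- read_plate_csv(opts$plate)
  if (!is.null(opts$layout)) grid <- apply_layout(grid, opts$layout)
  grid
}

cli_dispatch <- function(sub, opts) {
  out <- cli_out_dir(opts)
  inputs <- unlist(opts[intersect(names(opts), c("plate", "layout", "regions"))])

  if (sub == "simulate") {
    cli_require(opts, "mode")
    seed <- as.integer(opts$seed %||% cli_defaults$seed)
    noise <- noise_model(
      cv = opts$cv %||% cli_defaults$noise_cv,
      channel_cv = opts$channel_cv %||% cli_defaults$noise_channel_cv,
      seed = seed
    )
    sim <- switch(as.character(opts$mode),
      redox = {
        layout <- default_redox_layout(seed)
        simulate_redox_plate(layout, noise = noise)
      },
      ph = {
        layout <- default_ph_layout(seed)
        simulate_ph_plate(layout, noise = noise)
      },
      tfb = {
        layout <- default_tfb_layout()
        simulate_tfb_plate(layout, models = default_tfb_models(), noise = noise)
      },
      dilution = simulate_dilution_series(
        tibble(
          strain = c("WT_sensor", "mutant_sensor"),
          ratio = c(1.05, 1.45)
        ),
        noise = noise
      ),
      abort(paste0("Unknown simulate mode: ", opts$mode),
        class = "platesensor_usage_error"
      )
    )
    write_plate_csv(sim, file.path(out, "plate.csv"))
    lay <- dplyr::distinct(
      as_tibble(sim),
      dplyr::across(dplyr::all_of(c("well", intersect(layout_columns, names(sim)))))
    )
    write_layout_csv(lay, file.path(out, "layout.csv"))
  } else if (sub == "ratio") {
    grid <- cli_load_plate(opts)
    r <- plate_ratios(
      grid,
      opts$num %||% cli_defaults$numerator_nm,
      opts$den %||% cli_defaults$denominator_nm
    )
    readr::write_csv(r, file.path(out, "ratios.csv"), progress = FALSE)
  } else if (sub == "calibrate-ph") {
    grid <- cli_load_plate(opts)
    r <- plate_ratios(
      grid,
      opts$num %||% cli_defaults$numerator_nm,
      opts$den %||% cli_defaults$denominator_nm
    )
    std <- dplyr::filter(r, .data$role == "ph_standard")
    if (nrow(std) == 0) {
      abort("No wells with role 'ph_standard' on this plate.")
    }
    curve <- fit_ph_calibration(tibble(ph = std$role_value, ratio = std$ratio))
    jsonlite::write_json(
      c(as.list(glance(curve)), list(slope = curve$slope, intercept = curve$intercept)),
      file.path(out, "calibration.json"),
      auto_unbox = TRUE, digits = NA
    )
  } else if (sub == "ph-map") {
    grid <- cli_load_plate(opts)
    cm <- colony_map(grid, "ph")
    render_heatmap(cm$values, file.path(out, "ph_map.csv"), name = "pH")
    jsonlite::write_json(as.list(cm$summary), file.path(out, "ph_summary.json"),
      auto_unbox = TRUE, digits = NA
    )
  } else if (sub == "oxd") {
    grid <- cli_load_plate(opts)
    o <- plate_oxd(grid)
    readr::write_csv(o, file.path(out, "oxd.csv"), progress = FALSE)
    cm <- colony_map(grid, "oxd")
    render_heatmap(cm$values, file.path(out, "oxd_map.csv"), name = "OxD")
  } else if (sub == "dose-response") {
    grid <- cli_load_plate(opts)
    df <- dplyr::filter(as_tibble(grid), .data$role == "sample")
    fits <- purrr::map_dfr(split(df, df$strain), function(d) {
      if (length(unique(d$dose)) >= 4 && any(d$dose == 0)) {
        fit <- fit_hill(d$dose, d$intensity)
        tibble(
          strain = d$strain[1], model = "hill",
          F0 = fit$F0, Fmax = fit$Fmax, K = fit$K, n = fit$n,
          rss = fit$rss, converged = fit$converged
        )
      } else {
        lin <- fit_linear(d$dose, d$intensity)
        tibble(
          strain = d$strain[1], model = "linear",
          F0 = lin$intercept, Fmax = NA_real_, K = NA_real_, n = lin$slope,
          rss = NA_real_, converged = TRUE
        )
      }
    })
    readr::write_csv(fits, file.path(out, "dose_response.csv"), progress = FALSE)
  } else if (sub == "kinetics") {
    cli_require(opts, c("plate", "treatment_time"))
    raw <- readr::read_csv(opts$plate, show_col_types = FALSE, progress = FALSE)
    calls <- purrr::map_dfr(split(raw, raw$well), function(d) {
      tr <- trace_from_readings(
        d,
        numerator_nm = opts$num %||% cli_defaults$redox_numerator_nm,
        denominator_nm = opts$den %||% cli_defaults$redox_denominator_nm,
        treatment_time_s = opts$treatment_time, label = d$well[1]
      )
      cls <- classify_redox_response(
        tr,
        delta_threshold = opts$delta_threshold %||% cli_defaults$delta_threshold,
        band = opts$band %||% cli_defaults$band
      )
      dplyr::mutate(cls, well = d$well[1], .before = 1)
    })
    readr::write_csv(calls, file.path(out, "kinetic_calls.csv"), progress = FALSE)
  } else if (sub == "sizes") {
    cli_require(opts, "regions")
    regions <- readr::read_csv(opts$regions, show_col_types = FALSE, progress = FALSE)
    readr::write_csv(relative_sizes(regions), file.path(out, "relative_sizes.csv"),
      progress = FALSE
    )
  } else if (sub == "report") {
    grid <- cli_load_plate(opts)
    num <- opts$num %||% cli_defaults$numerator_nm
    den <- opts$den %||% cli_defaults$denominator_nm
    r <- plate_ratios(grid, num, den)
    samples <- dplyr::filter(r, .data$role == "sample")
    cmp <- compare_groups(samples, value = "ratio", group = "strain")
    readr::write_csv(cmp$groups, file.path(out, "group_means.csv"), progress = FALSE)
    readr::write_csv(cmp$pairwise, file.path(out, "tukey.csv"), progress = FALSE)
    jsonlite::write_json(as.list(cmp$anova), file.path(out, "anova.json"),
      auto_unbox = TRUE, digits = NA
    )
    ref <- opts$reference %||% cmp$groups$group[1]
    folds <- purrr::map_dfr(
      setdiff(cmp$groups$group, ref),
      function(g) {
        dplyr::mutate(
          fold_change(
            samples$ratio[samples$strain == g],
            samples$ratio[samples$strain == ref]
          ),
          strain = g, reference = ref, .before = 1
        )
      }
    )
    readr::write_csv(folds, file.path(out, "fold_changes.csv"), progress = FALSE)
    cm <- colony_map(grid, "ratio", numerator_nm = num, denominator_nm = den)
    render_heatmap(cm$values, file.path(out, "ratio_map.csv"), name = "ratio")
  }

  write_manifest(out, sub, opts, inputs = inputs)
  invisible(NULL)
}

# Bundled default layouts for `simulate` -------------------------------------

default_redox_layout <- function(seed = 0) {
  wells <- well_labels(96)
  layout <- tibble(well = wells, role = "sample", strain = "WT_sensor")
  layout$strain[61:96] <- "mutant_sensor"
  layout$role[1:4] <- "reduced_control"
  layout$role[5:8] <- "oxidized_control"
  layout$strain[1:8] <- "control"
  layout$oxd <- ifelse(layout$strain == "mutant_sensor", 0.93, 0.33)
  layout$oxd[1:8] <- NA
  with_seed(seed + 7L, {
    layout$brightness <- stats::runif(nrow(layout), 0.8, 1.2)
    layout
  })
}

default_ph_layout <- function(seed = 0) {
  wells <- well_labels(96)
  layout <- tibble(well = wells, role = "sample", strain = "sensor")
  std_ph <- rep(c(7.0, 7.5, 8.0, 8.5), each = 3)
  layout$role[1:12] <- "ph_standard"
  layout$role_value <- NA_real_
  layout$role_value[1:12] <- std_ph
  with_seed(seed + 11L, {
    layout$ph <- NA_real_
    layout$ph[13:96] <- stats::rnorm(84, 7.65, 0.03)
    layout$brightness <- stats::runif(nrow(layout), 0.8, 1.2)
    layout
  })
}

default_tfb_layout <- function() {
  wells <- well_labels(96)
  doses <- rep(c(0, 0.01, 0.025, 0.05, 0.1, 0.25, 0.5, 1, 2.5, 5, 0.075, 0.75), 8)
  strain <- rep(c("EV", "EV", "low_mcherry", "low_mcherry", "high_mcherry", "high_mcherry", "EV", "high_mcherry"),
    each = 12
  )
  tibble(well = wells, strain = strain, dose = doses, role = "sample")
}

default_tfb_models <- function() {
  list(
    EV = tfb_model(F0 = 4.96e3, Fmax = 0, K = 0.1, n = 1.5),
    low_mcherry = tfb_model(F0 = 4.96e3, Fmax = 1.63e4, K = 0.1, n = 1.5),
    high_mcherry = tfb_model(F0 = 4.96e3, Fmax = 1.93e5, K = 0.1, n = 1.5)
  )
}
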