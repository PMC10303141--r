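# Shared fixture builders (all fixtures are generated in code).

noiseless <- function(seed = 0) noise_model(cv = 0, channel_cv = 0, seed = seed)

# A minimal endpoint plate: each well gets readings at the given excitation
# wavelengths with supplied intensities.
make_plate <- function(wells, excitations, intensities, emission = 510,
                       plate_id = "test", format = 96) {
  stopifnot(length(intensities) == length(wells) * length(excitations))
  plate_grid(
    tibble::tibble(
      well = rep(wells, each = length(excitations)),
      excitation_nm = rep(excitations, length(wells)),
      emission_nm = emission,
      time_s = NA_real_,
      intensity = intensities
    ),
    plate_id = plate_id, format = format
  )
}

# Randomized plate for round-trip properties.
random_plate <- function(seed, n_wells = 24, format = 96) {
  set.seed(seed)
  wells <- sample(well_labels(format), n_wells)
  make_plate(
    wells,
    excitations = c(380, 470),
    intensities = stats::runif(n_wells * 2, 10, 1e7),
    format = format
  )
}

# Layout in the style of a three-strain screening plate (rows A-H).
three_strain_layout <- function(format = 96) {
  wells <- well_labels(format)
  n <- length(wells)
  tibble::tibble(
    well = wells,
    strain = rep(c("background", "weak", "strong"), length.out = n),
    role = "sample"
  )
}
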