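# Hierarchical synthetic spectra generator. Emulates a pulsed-lamp /
# fiber-probe acquisition: a smooth lamp continuum with narrow emission
# lines, a dark offset, tissue reflectance shaped by scattering and
# hemoglobin absorption bands (Soret 410 nm, Q-bands 540/580 nm), log-normal
# specimen- and spot-level albedo effects, and detector noise that grows
# beyond the visible window.

#' Describe one tissue type for the generator
#'
#' A tissue is summarized by a handful of unitless optical parameters. The
#' noiseless reflectance is
#' `100 * clamp(specimen * (lipid + baseline * (lambda/500)^-b) *
#'   exp(-spot * blood * eps(lambda)), 0, 1)`,
#' where `eps` is a pseudo-extinction curve with Gaussian hemoglobin bands
#' at 410, 540 and 580 nm (see [true_reflectance()]).
#'
#' @param name Tissue label, unique within a scenario.
#' @param baseline_amplitude Reflectance scale in (0, 1].
#' @param scatter_exponent Power-law exponent `b >= 0` of the
#'   `(lambda/500)^-b` scattering slope.
#' @param blood_fraction Hemoglobin absorber strength in \[0, 1\].
#' @param oxygenation Oxy/deoxy balance in \[0, 1\]; shifts weight between
#'   the 540 and 580 nm bands.
#' @param lipid_offset Additive broadband reflectance term, `>= 0`.
#' @return A `tissue_model` list.
#' @export
tissue_model <- function(name, baseline_amplitude, scatter_exponent,
                         blood_fraction, oxygenation = 0.5, lipid_offset = 0) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    drs_abort("tissue name must be a non-empty string", "invalid_argument")
  }
  chk <- function(x, lo, hi, nm, lo_open = FALSE) {
    ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
      (if (lo_open) x > lo else x >= lo) && x <= hi
    if (!ok) {
      drs_abort(sprintf("%s must be in %s%g, %g]", nm,
                        if (lo_open) "(" else "[", lo, hi),
                "invalid_argument")
    }
  }
  chk(baseline_amplitude, 0, 1, "baseline_amplitude", lo_open = TRUE)
  chk(scatter_exponent, 0, Inf, "scatter_exponent")
  chk(blood_fraction, 0, 1, "blood_fraction")
  chk(oxygenation, 0, 1, "oxygenation")
  chk(lipid_offset, 0, Inf, "lipid_offset")
  structure(
    list(name = name, baseline_amplitude = baseline_amplitude,
         scatter_exponent = scatter_exponent, blood_fraction = blood_fraction,
         oxygenation = oxygenation, lipid_offset = lipid_offset),
    class = "tissue_model")
}

# Pseudo-extinction curve: three Gaussian bands at 410/540/580 nm with
# widths 18/12/12 nm. Relative heights 1.0/0.25/0.22 at oxygenation 0.5;
# oxygenation shifts weight between the two Q-bands. The overall amplitude
# (5 optical-density units at the Soret peak for blood_fraction = 1) sets
# how deep the bands cut at full absorber strength.
pseudo_extinction <- function(grid, oxygenation = 0.5) {
  gauss <- function(center, width) exp(-((grid - center)^2) / (2 * width^2))
  h540 <- 0.25 + 0.10 * (oxygenation - 0.5)
  h580 <- 0.22 - 0.10 * (oxygenation - 0.5)
  5 * (gauss(410, 18) + h540 * gauss(540, 12) + h580 * gauss(580, 12))
}

#' Noiseless diffuse reflectance of a tissue model
#'
#' @param model A [tissue_model()].
#' @param grid Strictly increasing wavelengths (nm).
#' @param specimen_effect,spot_effect Positive multiplicative albedo
#'   effects (1 = the tissue's nominal optics).
#' @return Reflectance in percent, clamped to \[0, 100\], one value per
#'   wavelength.
#' @export
true_reflectance <- function(model, grid, specimen_effect = 1, spot_effect = 1) {
  if (!inherits(model, "tissue_model")) {
    drs_abort("model must be a tissue_model", "invalid_argument")
  }
  if (!length(grid) || any(diff(grid) <= 0)) {
    drs_abort("grid must be non-empty and strictly increasing", "invalid_argument")
  }
  for (eff in c(specimen_effect, spot_effect)) {
    if (!is.finite(eff) || eff <= 0) {
      drs_abort("specimen_effect and spot_effect must be positive", "invalid_argument")
    }
  }
  base <- model$lipid_offset +
    model$baseline_amplitude * (grid / 500)^(-model$scatter_exponent)
  att <- exp(-spot_effect * model$blood_fraction *
               pseudo_extinction(grid, model$oxygenation))
  100 * pmin(pmax(specimen_effect * base * att, 0), 1)
}

#' Acquisition design: how many samples, spots and repeats
#'
#' Defaults mirror a typical ex vivo protocol: 12 tissue samples per tissue
#' type, 6 probed spots per sample, 30 repeat spectra per spot, so four
#' tissue types yield 8640 spectra (2160 per tissue, 180 per sample).
#' Specimen- and spot-level albedo variation is multiplicative log-normal.
#'
#' @param tissue_models List of [tissue_model()]s with unique names.
#' @param samples_per_tissue,spots_per_sample,repeats_per_spot Counts, `>= 1`.
#' @param seed Master integer seed; all draws derive from it through
#'   per-(tissue, specimen, spot) sub-streams, so enlarging
#'   `repeats_per_spot` does not perturb earlier draws.
#' @param sigma_specimen,sigma_spot Log-scale standard deviations of the
#'   specimen and spot effects (defaults 0.10 and 0.05).
#' @return An `acquisition_design` list.
#' @export
acquisition_design <- function(tissue_models, samples_per_tissue = 12,
                               spots_per_sample = 6, repeats_per_spot = 30,
                               seed = 1L, sigma_specimen = 0.10,
                               sigma_spot = 0.05) {
  counts <- c(samples_per_tissue, spots_per_sample, repeats_per_spot)
  if (any(counts < 1) || any(counts != round(counts))) {
    drs_abort("design counts must be integers >= 1", "invalid_argument")
  }
  if (!length(tissue_models) ||
      !all(vapply(tissue_models, inherits, logical(1), "tissue_model"))) {
    drs_abort("tissue_models must be a non-empty list of tissue_model objects",
              "invalid_argument")
  }
  nms <- vapply(tissue_models, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    drs_abort("tissue model names must be unique", "invalid_argument")
  }
  if (sigma_specimen < 0 || sigma_spot < 0) {
    drs_abort("sigma_specimen and sigma_spot must be >= 0", "invalid_argument")
  }
  structure(
    list(tissue_models = setNames(tissue_models, nms),
         samples_per_tissue = as.integer(samples_per_tissue),
         spots_per_sample = as.integer(spots_per_sample),
         repeats_per_spot = as.integer(repeats_per_spot),
         seed = as.integer(seed),
         sigma_specimen = sigma_specimen, sigma_spot = sigma_spot),
    class = "acquisition_design")
}

# Default wavelength grid: spacing 300/1149 nm, anchored so 350 and 650 nm
# are grid points and exactly 1150 points fall in [350, 650], extended at
# the same spacing to roughly 200-900 nm (2681 points). Rounded to the
# package-wide 4-decimal wavelength precision.
default_grid <- function() {
  round(350 + (-574:2106) * (300 / 1149), 4)
}

#' Instrument model: lamp, dark offset and detector noise
#'
#' The lamp reference is a smooth continuum plus narrow Gaussian emission
#' lines (stand-ins for the line structure of a pulsed xenon lamp). Detector
#' noise is Gaussian with a flat floor that grows linearly beyond
#' `nir_noise_onset`, reproducing the poor signal-to-noise of the
#' near-infrared region that motivates cropping at 650 nm.
#'
#' @param wavelength_grid Strictly increasing grid (nm) covering at least
#'   350-650 nm.
#' @param lamp_continuum Counts per wavelength (vector matching the grid),
#'   or `NULL` for the built-in smooth continuum.
#' @param lamp_lines Tibble/data frame with columns `center`, `width`,
#'   `height` (nm, nm, counts).
#' @param dark_level Dark/background counts.
#' @param noise_floor_sd Flat detector noise sd (counts).
#' @param nir_noise_onset Wavelength (nm) beyond which noise grows.
#' @param nir_noise_slope Added noise sd per nm beyond the onset.
#' @return An `instrument_model` list with precomputed `reference_counts`
#'   (`S_R`) and `dark_counts` (`S_D`) on the grid.
#' @export
instrument_model <- function(wavelength_grid = default_grid(),
                             lamp_continuum = NULL,
                             lamp_lines = default_lamp_lines(),
                             dark_level = 400,
                             noise_floor_sd = 25,
                             nir_noise_onset = 650,
                             nir_noise_slope = 0.8) {
  grid <- round(wavelength_grid, 4)
  if (any(diff(grid) <= 0)) {
    drs_abort("wavelength_grid must be strictly increasing", "invalid_argument")
  }
  if (min(grid) > 350 || max(grid) < 650) {
    drs_abort("wavelength_grid must cover 350-650 nm", "coverage_error")
  }
  if (is.null(lamp_continuum)) {
    lamp_continuum <- 8000 + 14000 * exp(-((grid - 480) / 160)^2)
  }
  if (length(lamp_continuum) != length(grid)) {
    drs_abort("lamp_continuum must match the wavelength grid", "alignment_error")
  }
  lamp_lines <- tibble::as_tibble(lamp_lines)
  lines <- rep(0, length(grid))
  for (i in seq_len(nrow(lamp_lines))) {
    lines <- lines + lamp_lines$height[i] *
      exp(-((grid - lamp_lines$center[i])^2) / (2 * lamp_lines$width[i]^2))
  }
  reference <- dark_level + lamp_continuum + lines
  in_window <- grid >= 350 & grid <= 650
  if (any(reference[in_window] <= dark_level)) {
    drs_abort("lamp reference must exceed the dark level on 350-650 nm",
              "invalid_argument")
  }
  structure(
    list(wavelength_grid = grid, lamp_continuum = lamp_continuum,
         lamp_lines = lamp_lines, dark_level = dark_level,
         noise_floor_sd = noise_floor_sd, nir_noise_onset = nir_noise_onset,
         nir_noise_slope = nir_noise_slope,
         reference_counts = reference,
         dark_counts = rep(dark_level, length(grid))),
    class = "instrument_model")
}

#' @rdname instrument_model
#' @export
default_lamp_lines <- function() {
  tibble::tibble(
    center = c(452, 462, 473, 484, 494, 830, 860, 885),
    width  = c(1.5, 1.5, 1.5, 1.5, 1.5, 2, 2, 2),
    height = c(2500, 3200, 2800, 2200, 2600, 3000, 3500, 2800))
}

noise_sd_at <- function(instrument, grid) {
  instrument$noise_floor_sd +
    instrument$nir_noise_slope * pmax(0, grid - instrument$nir_noise_onset)
}

#' Simulate a raw spectra dataset plus reference/dark curves
#'
#' Draws, for every tissue sample, a log-normal specimen effect; for every
#' spot, a log-normal spot effect; and for every repeat, a raw signal
#' `S_Rd = Rd_true/100 * (S_R - S_D) + S_D + noise`, with heteroscedastic
#' Gaussian detector noise. Fully reproducible from the design seed.
#'
#' @param design An [acquisition_design()].
#' @param instrument An [instrument_model()].
#' @return A list with `spectra` (wide tibble, stage `"raw"`) and
#'   `reference` (tibble with `wavelength`, `reference`, `dark`).
#' @export
simulate_dataset <- function(design, instrument = instrument_model()) {
  if (!inherits(design, "acquisition_design")) {
    drs_abort("design must be an acquisition_design", "invalid_argument")
  }
  if (!inherits(instrument, "instrument_model")) {
    drs_abort("instrument must be an instrument_model", "invalid_argument")
  }
  grid <- instrument$wavelength_grid
  p <- length(grid)
  signal_span <- instrument$reference_counts - instrument$dark_counts
  noise_sd <- noise_sd_at(instrument, grid)
  n_per_sample <- design$spots_per_sample * design$repeats_per_spot
  n_total <- length(design$tissue_models) * design$samples_per_tissue * n_per_sample

  m <- matrix(0, nrow = n_total, ncol = p)
  tissue <- character(n_total); specimen <- character(n_total)
  spot <- character(n_total); rep_idx <- integer(n_total)
  row <- 0L
  for (model in design$tissue_models) {
    for (i in seq_len(design$samples_per_tissue)) {
      spec_id <- sprintf("%s_s%02d", model$name, i)
      set.seed(substream_seed(design$seed, model$name, i, "specimen"))
      specimen_effect <- rlnorm(1, 0, design$sigma_specimen)
      for (j in seq_len(design$spots_per_sample)) {
        set.seed(substream_seed(design$seed, model$name, i, j, "spot"))
        spot_effect <- rlnorm(1, 0, design$sigma_spot)
        rd <- true_reflectance(model, grid, specimen_effect, spot_effect)
        clean <- rd / 100 * signal_span + instrument$dark_counts
        # repeat-major draw order so enlarging repeats_per_spot only appends
        noise <- matrix(rnorm(design$repeats_per_spot * p,
                              sd = rep(noise_sd, times = design$repeats_per_spot)),
                        nrow = design$repeats_per_spot, byrow = TRUE)
        rows <- row + seq_len(design$repeats_per_spot)
        m[rows, ] <- matrix(clean, nrow = design$repeats_per_spot,
                            ncol = p, byrow = TRUE) + noise
        tissue[rows] <- model$name
        specimen[rows] <- spec_id
        spot[rows] <- sprintf("spot%d", j)
        rep_idx[rows] <- seq_len(design$repeats_per_spot)
        row <- row + design$repeats_per_spot
      }
    }
  }
  meta <- tibble::tibble(tissue = tissue, specimen_id = specimen,
                         spot_id = spot, repeat_index = rep_idx)
  spectra <- new_spectra(meta, m, grid, stage = "raw")
  reference <- tibble::tibble(wavelength = grid,
                              reference = instrument$reference_counts,
                              dark = instrument$dark_counts)
  list(spectra = spectra, reference = reference)
}

#' Built-in simulation scenarios
#'
#' Three named bundles of design + instrument:
#' * `"paperlike"` — four mid-facial tissues with qualitatively realistic
#'   contrasts: cancellous bone is hemoglobin-dominated (largest
#'   `blood_fraction`), cortical bone is a flat high-reflectance spectrum
#'   deliberately close in shape to nerve (the hard pairs), nerve and
#'   salivary gland share a similar lipid offset.
#' * `"separable"` — four widely spaced tissue models; every pair should be
#'   near-perfectly classifiable.
#' * `"null"` — four tissue labels sharing one identical model; pairwise
#'   discrimination should sit at chance.
#'
#' The parameter values are invented calibration, not measured optical
#' properties; they are tuned only to reproduce qualitative orderings.
#'
#' @param seed Master seed stored in each design.
#' @return Named list of `list(design, instrument)` bundles.
#' @export
default_scenarios <- function(seed = 1L) {
  # cortical bone is an amplitude-scaled (x1.19) copy of the nerve optics:
  # the two differ only through overall albedo, which is confounded with
  # specimen-level variation -- the hard pairs of the report.
  paperlike <- list(
    tissue_model("cortical_bone", 0.4998, 0.50, 0.10, 0.60, 0.1428),
    tissue_model("nerve",          0.42, 0.50, 0.10, 0.60, 0.12),
    tissue_model("salivary_gland", 0.40, 0.80, 0.25, 0.65, 0.10),
    tissue_model("cancellous_bone", 0.33, 0.60, 0.60, 0.70, 0.04))
  separable <- list(
    tissue_model("cortical_bone", 0.85, 0.10, 0.02, 0.50, 0.10),
    tissue_model("nerve",          0.30, 1.50, 0.10, 0.20, 0.30),
    tissue_model("salivary_gland", 0.55, 0.80, 0.45, 0.90, 0.02),
    tissue_model("cancellous_bone", 0.20, 0.40, 0.90, 0.60, 0.00))
  shared <- list(0.42, 0.50, 0.15, 0.60, 0.10)
  null <- lapply(c("cortical_bone", "nerve", "salivary_gland", "cancellous_bone"),
                 function(nm) do.call(tissue_model, c(list(nm), shared)))
  instr <- instrument_model()
  list(
    paperlike = list(design = acquisition_design(paperlike, seed = seed),
                     instrument = instr),
    separable = list(design = acquisition_design(separable, seed = seed),
                     instrument = instr),
    null = list(design = acquisition_design(null, seed = seed),
                instrument = instr))
}

#' @rdname default_scenarios
#' @param name Scenario name.
#' @export
scenario <- function(name, seed = 1L) {
  sc <- default_scenarios(seed = seed)
  if (!name %in% names(sc)) {
    drs_abort(sprintf("unknown scenario '%s'; available: %s", name,
                      paste(names(sc), collapse = ", ")),
              "usage_error")
  }
  sc[[name]]
}
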