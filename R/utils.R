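# Shared internal helpers: condition classes, the wide spectra container,
# wavelength-column conventions, deterministic seed sub-streams.

drs_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("drs_", class), "drs_error"), ...)
}

drs_warn <- function(message, class, ...) {
  rlang::warn(message, class = c(paste0("drs_", class), "drs_warning"), ...)
}

# Wavelength columns are named by their nm value with exactly 4 decimals;
# this is the canonical precision of every grid in the package, so column
# names round-trip grids exactly through text files.
wl_name <- function(wl) sprintf("%.4f", wl)

is_wl_name <- function(x) grepl("^[0-9]+\\.[0-9]{4}$", x)

#' Wavelength grid of a spectra table
#'
#' Spectra live in wide tibbles: metadata columns (`tissue`, `specimen_id`,
#' `spot_id`, `repeat_index`) followed by one intensity column per wavelength,
#' named by the wavelength in nm with 4 decimals. These helpers pull the
#' numeric grid, the intensity matrix, and the metadata back out.
#'
#' @param x A spectra tibble (as produced by [simulate_dataset()],
#'   [read_spectra()] or the preprocessing functions).
#' @return `spectra_wavelengths()`: numeric vector of wavelengths (nm);
#'   `spectra_matrix()`: numeric matrix, observations in rows;
#'   `spectra_meta()`: tibble of the non-wavelength columns.
#' @export
spectra_wavelengths <- function(x) {
  as.numeric(names(x)[is_wl_name(names(x))])
}

#' @rdname spectra_wavelengths
#' @export
spectra_matrix <- function(x) {
  cols <- names(x)[is_wl_name(names(x))]
  m <- as.matrix(x[cols])
  storage.mode(m) <- "double"
  m
}

#' @rdname spectra_wavelengths
#' @export
spectra_meta <- function(x) {
  tibble::as_tibble(x[!is_wl_name(names(x))])
}

#' Processing stage of a spectra table
#'
#' Each spectra tibble carries a `stage` attribute, one of `"raw"`
#' (detector counts), `"reflectance"` (percent) or `"standardized"`
#' (z-scores). The stage is preserved by [write_spectra()] /
#' [read_spectra()] via a comment header.
#'
#' @param x A spectra tibble.
#' @return A string, or `"raw"` when the attribute is absent.
#' @export
spectra_stage <- function(x) attr(x, "stage") %||% "raw"

new_spectra <- function(meta, m, wavelengths, stage) {
  stopifnot(nrow(meta) == nrow(m) || (nrow(meta) == 0L && nrow(m) == 0L))
  colnames(m) <- wl_name(wavelengths)
  out <- dplyr::bind_cols(meta, tibble::as_tibble(m, .name_repair = "minimal"))
  set_stage(out, stage)
}

set_stage <- function(x, stage) {
  attr(x, "stage") <- stage
  class(x) <- unique(c("drs_spectra", class(tibble::tibble())))
  x
}

validate_spectra <- function(x, where = "spectra") {
  wl <- spectra_wavelengths(x)
  if (length(wl) < 2L) {
    drs_abort(sprintf("%s must have at least 2 wavelength columns", where),
              "format_error")
  }
  bad <- which(diff(wl) <= 0)
  if (length(bad)) {
    drs_abort(
      sprintf("%s wavelengths not strictly increasing at column '%s' (position %d)",
              where, wl_name(wl[bad[1] + 1L]), bad[1] + 1L),
      "format_error")
  }
  m <- spectra_matrix(x)
  if (nrow(m) && !all(is.finite(m))) {
    drs_abort(sprintf("%s contains non-finite intensities", where), "format_error")
  }
  if ("specimen_id" %in% names(x) && "tissue" %in% names(x) && nrow(x)) {
    map <- dplyr::distinct(tibble::as_tibble(x)[c("specimen_id", "tissue")])
    dup <- map$specimen_id[duplicated(map$specimen_id)]
    if (length(dup)) {
      drs_abort(sprintf("specimen_id '%s' maps to more than one tissue", dup[1]),
                "format_error")
    }
  }
  invisible(x)
}

# Deterministic sub-stream seeds: a small multiplicative hash of the master
# seed and a path of labels, kept below 2^31. Doubles hold the intermediate
# products exactly (< 2^53).
substream_seed <- function(master, ...) {
  h <- as.double(master %% 2147483647)
  for (part in as.character(c(...))) {
    for (k in utf8ToInt(part)) h <- (h * 31 + k) %% 2147483647
  }
  as.integer(h)
}
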