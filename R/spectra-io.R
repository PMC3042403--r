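# Plain-text formats. Spectra: one TSV row per acquisition (tissue,
# specimen_id, spot_id, repeat_index, then one intensity column per
# wavelength, named by the nm value with 4 decimals). Reference and dark:
# two-column TSVs (wavelength, counts). '#'-prefixed header lines carry
# provenance (tool version, stage) and are ignored on read.

meta_cols <- c("tissue", "specimen_id", "spot_id", "repeat_index")

io_header <- function(kind, stage = NULL) {
  h <- c(sprintf("# drspectra %s file (v%s)", kind,
                 as.character(utils::packageVersion("drspectra"))))
  if (!is.null(stage)) h <- c(h, sprintf("# stage: %s", stage))
  h
}

#' Write and read spectra tables
#'
#' Deterministic column order (metadata, then wavelengths ascending);
#' intensities round-trip exactly to at least 15 significant digits; stage
#' preserved through a `# stage:` comment line.
#'
#' @param x A spectra tibble.
#' @param path File path (TSV).
#' @return `write_spectra()`: the path, invisibly. `read_spectra()`: the
#'   spectra tibble with its `stage` attribute restored.
#' @export
write_spectra <- function(x, path) {
  validate_spectra(x)
  wl <- spectra_wavelengths(x)
  keep_meta <- intersect(meta_cols, names(x))
  out <- tibble::as_tibble(x)[c(keep_meta, wl_name(wl))]
  tryCatch({
    writeLines(io_header("spectra", stage = spectra_stage(x)), path)
    readr::write_tsv(out, path, append = TRUE, col_names = TRUE, progress = FALSE)
  }, error = function(e) {
    drs_abort(sprintf("cannot write '%s': %s", path, conditionMessage(e)), "io_error")
  })
  invisible(path)
}

read_comment_stage <- function(path) {
  stage <- NULL
  con <- file(path, "r"); on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line) || !startsWith(line, "#")) break
    m <- regmatches(line, regexec("^#\\s*stage:\\s*(\\S+)", line))[[1]]
    if (length(m) == 2L) stage <- m[2]
  }
  stage
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) {
    drs_abort(sprintf("file not found: '%s'", path), "io_error")
  }
  stage <- read_comment_stage(path)
  first <- readr::read_lines(path, n_max = 200, progress = FALSE)
  header_line <- first[!startsWith(first, "#")][1]
  if (is.na(header_line)) {
    drs_abort(sprintf("'%s': no header line found", path), "format_error")
  }
  cols <- strsplit(header_line, "\t", fixed = TRUE)[[1]]
  types <- do.call(readr::cols, c(
    list(.default = readr::col_double()),
    setNames(rep(list(readr::col_character()),
                 length(intersect(cols, c("tissue", "specimen_id", "spot_id")))),
             intersect(cols, c("tissue", "specimen_id", "spot_id"))),
    if ("repeat_index" %in% cols) list(repeat_index = readr::col_integer())))
  df <- suppressWarnings(
    readr::read_tsv(path, comment = "#", col_types = types, progress = FALSE))
  probs <- readr::problems(df)
  if (nrow(probs)) {
    drs_abort(sprintf("'%s': malformed row at line %d (%s)", path,
                      probs$row[1], probs$expected[1]),
              "format_error")
  }
  attr(df, "spec") <- NULL
  attr(df, "problems") <- NULL
  wl_cols <- cols[is_wl_name(cols)]
  if (length(wl_cols) < 2L) {
    drs_abort(sprintf("'%s': fewer than 2 wavelength columns in header", path),
              "format_error")
  }
  wl <- as.numeric(wl_cols)
  bad <- which(diff(wl) <= 0)
  if (length(bad)) {
    drs_abort(sprintf("'%s': wavelength columns not strictly increasing at column '%s' (header position %d)",
                      path, wl_cols[bad[1] + 1L],
                      match(wl_cols[bad[1] + 1L], cols)),
              "format_error")
  }
  out <- set_stage(df, stage %||% "raw")
  if (nrow(out)) validate_spectra(out, where = path)
  out
}

#' Write and read reference / dark curves
#'
#' @param reference Tibble with `wavelength`, `reference`, `dark` (as
#'   returned by [simulate_dataset()]), or for `read_reference()` two
#'   two-column TSV paths sharing one wavelength grid.
#' @param path_reference,path_dark File paths.
#' @param window Retained window (nm) inside which `reference > dark` is
#'   enforced; violations are flagged, not fatal.
#' @return `read_reference()`: tibble with `wavelength`, `reference`,
#'   `dark` and an attribute `flagged` listing wavelengths where the
#'   reference does not exceed the dark signal inside the window.
#' @export
write_reference <- function(reference, path_reference, path_dark) {
  stopifnot(all(c("wavelength", "reference", "dark") %in% names(reference)))
  wr <- function(df, path, kind) {
    writeLines(io_header(kind), path)
    readr::write_tsv(df, path, append = TRUE, col_names = TRUE, progress = FALSE)
  }
  wr(tibble::tibble(wavelength = round(reference$wavelength, 4),
                    counts = reference$reference), path_reference, "reference")
  wr(tibble::tibble(wavelength = round(reference$wavelength, 4),
                    counts = reference$dark), path_dark, "dark")
  invisible(c(path_reference, path_dark))
}

read_two_col <- function(path) {
  if (!file.exists(path)) {
    drs_abort(sprintf("file not found: '%s'", path), "io_error")
  }
  df <- suppressWarnings(readr::read_tsv(
    path, comment = "#", progress = FALSE,
    col_types = readr::cols(wavelength = readr::col_double(),
                            counts = readr::col_double())))
  probs <- readr::problems(df)
  if (nrow(probs) || !all(c("wavelength", "counts") %in% names(df))) {
    drs_abort(sprintf("'%s': expected two columns (wavelength, counts)", path),
              "format_error")
  }
  attr(df, "spec") <- NULL
  attr(df, "problems") <- NULL
  df
}

#' @rdname write_reference
#' @export
read_reference <- function(path_reference, path_dark, window = c(350, 650)) {
  ref <- read_two_col(path_reference)
  dark <- read_two_col(path_dark)
  if (nrow(ref) != nrow(dark) || !isTRUE(all.equal(ref$wavelength, dark$wavelength))) {
    drs_abort("reference and dark files do not share one wavelength grid",
              "alignment_error")
  }
  out <- tibble::tibble(wavelength = ref$wavelength,
                        reference = ref$counts, dark = dark$counts)
  in_win <- out$wavelength >= window[1] & out$wavelength <= window[2]
  flagged <- out$wavelength[in_win & out$reference <= out$dark]
  if (length(flagged)) {
    drs_warn(sprintf("reference does not exceed dark at %d wavelength(s) inside [%g, %g] nm",
                     length(flagged), window[1], window[2]),
             "degenerate_reference_warning")
  }
  attr(out, "flagged") <- flagged
  out
}
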