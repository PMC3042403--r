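# Raw counts -> percent reflectance -> informative window -> z-scores.

#' Convert raw counts to percent diffuse reflectance
#'
#' Applies the standard reflectance calibration
#' `R_d(lambda) = (S_Rd - S_D) / (S_R - S_D) * 100`
#' elementwise against the lamp reference `S_R` and dark background `S_D`,
#' which must share the raw spectra's wavelength grid exactly (no implicit
#' interpolation).
#'
#' @param x Raw spectra tibble (stage `"raw"`).
#' @param reference Tibble with `wavelength`, `reference`, `dark`.
#' @param tol Degenerate-reference tolerance: wavelengths where
#'   `|S_R - S_D| < tol * max(S_R)` raise an error instead of producing
#'   unbounded reflectance.
#' @return Spectra tibble in percent reflectance, stage `"reflectance"`,
#'   metadata carried over.
#' @export
compute_reflectance <- function(x, reference, tol = 1e-9) {
  wl <- spectra_wavelengths(x)
  ref_wl <- round(reference$wavelength, 4)
  if (length(wl) != length(ref_wl) || !all(wl == ref_wl)) {
    drs_abort("spectra and reference are not on the same wavelength grid",
              "alignment_error")
  }
  denom <- reference$reference - reference$dark
  degen <- which(abs(denom) < tol * max(reference$reference))
  if (length(degen)) {
    drs_abort(sprintf("reference and dark are indistinguishable at %d wavelength(s): %s%s",
                      length(degen),
                      paste(wl_name(wl[head(degen, 5)]), collapse = ", "),
                      if (length(degen) > 5) ", ..." else ""),
              "degenerate_reference")
  }
  m <- spectra_matrix(x)
  rd <- sweep(sweep(m, 2, reference$dark, "-"), 2, denom, "/") * 100
  new_spectra(spectra_meta(x), rd, wl, stage = "reflectance")
}

#' Crop spectra to a window, optionally onto a canonical uniform grid
#'
#' Wavelengths outside the window are dropped; the near-infrared region is
#' excluded because detector noise grows rapidly there. With
#' `resample = TRUE` the retained part is linearly interpolated onto a
#' uniform grid of `target_points` points spanning the window inclusive
#' (default 1150 points over 350-650 nm). Grid points shared between the
#' input and the canonical grid are copied, not interpolated, so the
#' operation is idempotent.
#'
#' @param x Spectra tibble whose grid spans the window.
#' @param window `c(min, max)` in nm.
#' @param target_points Number of output wavelengths when resampling.
#' @param resample If `FALSE`, pure cropping (keep in-window columns as-is).
#' @return Spectra tibble on the cropped grid; stage unchanged.
#' @export
crop_spectra <- function(x, window = c(350, 650), target_points = 1150,
                         resample = TRUE) {
  if (window[1] >= window[2] || target_points < 2) {
    drs_abort("window must satisfy min < max and target_points >= 2",
              "invalid_argument")
  }
  wl <- spectra_wavelengths(x)
  if (min(wl) > window[1] || max(wl) < window[2]) {
    drs_abort(sprintf("input grid [%g, %g] does not cover the window [%g, %g]",
                      min(wl), max(wl), window[1], window[2]),
              "coverage_error")
  }
  m <- spectra_matrix(x)
  if (!resample) {
    keep <- wl >= window[1] & wl <= window[2]
    return(new_spectra(spectra_meta(x), m[, keep, drop = FALSE], wl[keep],
                       stage = spectra_stage(x)))
  }
  target <- round(seq(window[1], window[2], length.out = target_points), 4)
  lo <- findInterval(target, wl, rightmost.closed = TRUE)
  exact <- wl[lo] == target
  hi <- pmin(lo + 1L, length(wl))
  w <- ifelse(exact, 0, (target - wl[lo]) / (wl[hi] - wl[lo]))
  out <- m[, lo, drop = FALSE] * rep(1 - w, each = nrow(m)) +
    m[, hi, drop = FALSE] * rep(w, each = nrow(m))
  new_spectra(spectra_meta(x), out, target, stage = spectra_stage(x))
}

#' Wavelength-wise standardization
#'
#' `fit_standardizer()` computes per-wavelength sample means and standard
#' deviations (n-1 denominator) on a training set; `apply_standardizer()`
#' maps any dataset on the same grid to z-scores
#' `z = (R_d - mean) / sd`. In cross-validation the standardizer is fitted
#' on the training fold only and applied to the held-out fold.
#'
#' Columns with sd below `1e-12` carry no information; their sd is set to 1
#' (so z = 0) with a warning.
#'
#' @param train Spectra tibble, `n >= 2` rows.
#' @param x Spectra tibble on the standardizer's grid.
#' @param params A `drs_standardizer`.
#' @return `fit_standardizer()`: a `drs_standardizer` (wavelengths, means,
#'   sds); `apply_standardizer()`: spectra tibble, stage `"standardized"`.
#' @export
fit_standardizer <- function(train) {
  m <- spectra_matrix(train)
  if (nrow(m) < 2L) {
    drs_abort("standardization needs at least 2 observations", "insufficient_data")
  }
  means <- colMeans(m)
  sds <- apply(m, 2, sd)
  degenerate <- sds < 1e-12
  if (any(degenerate)) {
    drs_warn(sprintf("%d constant wavelength column(s); sd set to 1",
                     sum(degenerate)),
             "degenerate_column")
    sds[degenerate] <- 1
  }
  structure(list(wavelengths = spectra_wavelengths(train),
                 means = unname(means), sds = unname(sds)),
            class = "drs_standardizer")
}

#' @rdname fit_standardizer
#' @export
apply_standardizer <- function(x, params) {
  stopifnot(inherits(params, "drs_standardizer"))
  wl <- spectra_wavelengths(x)
  if (length(wl) != length(params$wavelengths) || !all(wl == params$wavelengths)) {
    drs_abort("dataset is not on the standardizer's wavelength grid",
              "alignment_error")
  }
  m <- spectra_matrix(x)
  z <- sweep(sweep(m, 2, params$means, "-"), 2, params$sds, "/")
  new_spectra(spectra_meta(x), z, wl, stage = "standardized")
}

#' @export
tidy.drs_standardizer <- function(x, ...) {
  tibble::tibble(wavelength = x$wavelengths, mean = x$means, sd = x$sds)
}
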