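# ggplot2 visualisations for the main result types.

#' Plot mean spectra per tissue
#'
#' @param object Spectra tibble with a `tissue` column.
#' @param ... Unused.
#' @return A ggplot: mean intensity per wavelength and tissue, with a
#'   +/- 1 sd ribbon.
#' @export
autoplot.drs_spectra <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(dplyr::all_of(wl_name(spectra_wavelengths(object))),
                        names_to = "wavelength", values_to = "intensity") |>
    dplyr::mutate(wavelength = as.numeric(.data$wavelength)) |>
    dplyr::group_by(.data$tissue, .data$wavelength) |>
    dplyr::summarise(mean = mean(.data$intensity),
                     sd = sd(.data$intensity), .groups = "drop")
  ylab <- switch(spectra_stage(object),
                 raw = "counts (a.u.)",
                 reflectance = "diffuse reflectance (%)",
                 standardized = "standardized reflectance (z)")
  ggplot2::ggplot(long, ggplot2::aes(.data$wavelength, .data$mean,
                                     colour = .data$tissue,
                                     fill = .data$tissue)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = ylab, colour = "tissue",
                  fill = "tissue") +
    ggplot2::theme_minimal()
}

#' Plot principal-component loadings over wavelength
#'
#' @param object A `drs_pca` fitted on a spectra tibble.
#' @param components Which components to draw.
#' @param ... Unused.
#' @export
autoplot.drs_pca <- function(object, components = 1:3, ...) {
  components <- components[components <= object$k]
  x <- object$wavelengths %||% seq_len(object$p)
  long <- purrr::map_dfr(components, function(j) {
    tibble::tibble(wavelength = x, component = factor(paste0("PC", j)),
                   loading = object$loadings[, j])
  })
  ggplot2::ggplot(long, ggplot2::aes(.data$wavelength, .data$loading,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = if (is.null(object$wavelengths)) "variable" else "wavelength (nm)",
                  y = "loading") +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve with its Youden-optimal point
#'
#' @param object A `drs_roc`.
#' @param ... Unused.
#' @export
autoplot.drs_roc <- function(object, ...) {
  curve <- object$curve
  ggplot2::ggplot(curve, ggplot2::aes(1 - .data$specificity, .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::annotate("point", x = 1 - object$youden_spec,
                      y = object$youden_sens, colour = "red", size = 2) +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("AUC = %.3f, J = %.3f",
                                  object$auc, object$youden_J)) +
    ggplot2::theme_minimal()
}
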