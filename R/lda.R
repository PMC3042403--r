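# Multiclass linear discriminant analysis on selected principal-component
# scores. The generative view: class-conditional Gaussians with a shared
# (pooled within-class) covariance, which maximizes the ratio of between-
# to within-class variance and yields closed-form posteriors. Posteriors
# are reported instead of hard labels so downstream ROC analysis can sweep
# thresholds.

#' Fit a linear discriminant model
#'
#' Class means and the pooled within-class covariance (n - c denominator)
#' are estimated from the training scores. A small ridge
#' `eps = regularization * trace(Sigma)/k` is added to the covariance
#' diagonal to guard degenerate folds; selected-PC scores are near
#' orthogonal, so the pooled covariance is normally well conditioned and
#' the ridge is negligible.
#'
#' @param z `n x k` numeric score matrix.
#' @param labels Class label per row; at least two classes with at least
#'   two observations each.
#' @param priors `NULL` for empirical class frequencies, `"equal"`, or a
#'   named/ordered numeric vector summing to 1.
#' @param regularization Relative ridge (default `1e-8`).
#' @return A `drs_lda` with `class_labels`, `class_means`,
#'   `pooled_covariance`, `priors`.
#' @export
fit_lda <- function(z, labels, priors = NULL, regularization = 1e-8) {
  z <- as.matrix(z)
  labels <- as.character(labels)
  if (length(labels) != nrow(z)) {
    drs_abort("labels must have one entry per score row", "alignment_error")
  }
  if (ncol(z) < 1L) drs_abort("need k >= 1 score columns", "invalid_argument")
  classes <- unique(labels)
  if (length(classes) < 2L) {
    drs_abort("LDA needs at least two classes", "invalid_argument")
  }
  counts <- table(factor(labels, levels = classes))
  small <- names(counts)[counts < 2]
  if (length(small)) {
    drs_abort(sprintf("class '%s' has fewer than 2 observations", small[1]),
              "insufficient_data")
  }
  n <- nrow(z); k <- ncol(z); c <- length(classes)
  means <- matrix(0, nrow = c, ncol = k,
                  dimnames = list(classes,
                                  colnames(z) %||% paste0("PC", seq_len(k))))
  pooled <- matrix(0, k, k)
  for (cl in classes) {
    zc <- z[labels == cl, , drop = FALSE]
    mu <- colMeans(zc)
    means[cl, ] <- mu
    pooled <- pooled + crossprod(sweep(zc, 2, mu, "-"))
  }
  pooled <- pooled / (n - c)
  eps <- regularization * mean(diag(pooled))
  pooled_reg <- pooled + diag(eps, k)
  chol_fac <- tryCatch(chol(pooled_reg), error = function(e) NULL)
  if (is.null(chol_fac)) {
    drs_abort("pooled covariance is singular even after regularization",
              "singular_model")
  }
  if (is.null(priors)) {
    priors <- as.numeric(counts) / n
  } else if (identical(priors, "equal")) {
    priors <- rep(1 / c, c)
  } else {
    if (!is.null(names(priors))) priors <- priors[classes]
    if (length(priors) != c || any(priors < 0) ||
        abs(sum(priors) - 1) > 1e-12) {
      drs_abort("priors must be non-negative, one per class, summing to 1",
                "invalid_argument")
    }
    priors <- as.numeric(priors)
  }
  structure(
    list(class_labels = classes, class_means = means,
         pooled_covariance = pooled_reg, chol = chol_fac,
         priors = setNames(priors, classes),
         regularization = regularization, k = k, n = n),
    class = "drs_lda")
}

#' Class posterior probabilities under a fitted LDA model
#'
#' `p(class | z) propto prior * exp(-0.5 * (z - mu)' Sigma^-1 (z - mu))`,
#' normalized per observation in log space (no overflow for extreme
#' scores). Rows sum to 1.
#'
#' @param model A `drs_lda`.
#' @param z Matrix (or vector) with the model's `k` columns.
#' @return Tibble with one probability column per class, rows in input
#'   order.
#' @export
predict_proba <- function(model, z) {
  stopifnot(inherits(model, "drs_lda"))
  if (is.null(dim(z))) z <- matrix(z, ncol = model$k)
  z <- as.matrix(z)
  if (ncol(z) != model$k) {
    drs_abort(sprintf("expected %d score columns, got %d", model$k, ncol(z)),
              "alignment_error")
  }
  classes <- model$class_labels
  logpost <- matrix(0, nrow = nrow(z), ncol = length(classes),
                    dimnames = list(NULL, classes))
  for (i in seq_along(classes)) {
    delta <- sweep(z, 2, model$class_means[classes[i], ], "-")
    # Mahalanobis via the Cholesky factor: solve U' w = delta'
    w <- backsolve(model$chol, t(delta), transpose = TRUE)
    logpost[, i] <- log(model$priors[i]) - 0.5 * colSums(w^2)
  }
  mx <- apply(logpost, 1, max)
  post <- exp(logpost - mx)
  post <- post / rowSums(post)
  tibble::as_tibble(post)
}

#' @export
tidy.drs_lda <- function(x, ...) {
  tibble::as_tibble(x$class_means, rownames = "class") |>
    tidyr::pivot_longer(-"class", names_to = "component", values_to = "mean")
}

#' @export
glance.drs_lda <- function(x, ...) {
  tibble::tibble(n_classes = length(x$class_labels), k = x$k, n = x$n,
                 regularization = x$regularization)
}

#' @export
print.drs_lda <- function(x, ...) {
  cat(sprintf("LDA model: %d classes (%s), %d component(s), n = %d\n",
              length(x$class_labels), paste(x$class_labels, collapse = ", "),
              x$k, x$n))
  invisible(x)
}
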