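# Pairwise ROC analysis of cross-validated class posteriors: renormalized
# two-class scores, empirical ROC curves, trapezoidal AUC (equal to the
# concordance probability with ties counted 1/2), and the Youden-optimal
# cutpoint J = sensitivity + specificity - 1.

#' Renormalized two-class score for one tissue pair
#'
#' Restricts the predictions to observations whose true label is one of
#' the pair and scores each as `p(pos) / (p(pos) + p(neg))` — invariant to
#' probability mass on other classes, and equal to the raw posterior in a
#' two-class problem.
#'
#' @param predictions Prediction tibble from [run_loocv()] (or a
#'   `drs_loocv`), with `tissue` and posterior columns `p_<class>`.
#' @param positive,negative Tissue labels of the pair; `positive` is the
#'   class scored towards 1.
#' @return Tibble with `observation`, `tissue`, `score`.
#' @export
pairwise_score <- function(predictions, positive, negative) {
  if (inherits(predictions, "drs_loocv")) predictions <- predictions$predictions
  for (cl in c(positive, negative)) {
    if (!paste0("p_", cl) %in% names(predictions) ||
        !cl %in% predictions$tissue) {
      drs_abort(sprintf("tissue '%s' absent from the predictions", cl),
                "invalid_argument")
    }
  }
  keep <- predictions$tissue %in% c(positive, negative)
  p_pos <- predictions[[paste0("p_", positive)]][keep]
  p_neg <- predictions[[paste0("p_", negative)]][keep]
  denom <- p_pos + p_neg
  score <- ifelse(denom > 0, p_pos / denom, 0.5)
  tibble::tibble(observation = predictions$observation[keep],
                 tissue = predictions$tissue[keep], score = score)
}

#' Empirical ROC curve with Youden-optimal cutpoint
#'
#' Thresholds are the distinct score values plus a sentinel above the
#' maximum; an observation is called positive when `score >= threshold`.
#' Sensitivity is the true-positive rate among positives, specificity the
#' true-negative rate among negatives. The Youden index
#' `J = sensitivity + specificity - 1` is maximized over thresholds; ties
#' are broken toward the higher-specificity threshold.
#'
#' @param score Numeric scores.
#' @param truth Logical vector (`TRUE` = positive) or a vector matching
#'   `positive`.
#' @param positive When `truth` is not logical, the label counted positive.
#' @return A `drs_roc`: `curve` (threshold, sensitivity, specificity),
#'   `auc`, `youden_cutpoint`, `youden_sens`, `youden_spec`, `youden_J`.
#' @export
roc_curve <- function(score, truth, positive = NULL) {
  if (!is.logical(truth)) {
    if (is.null(positive)) {
      drs_abort("supply a logical truth vector or the positive label",
                "invalid_argument")
    }
    truth <- truth == positive
  }
  if (length(score) != length(truth) || !all(is.finite(score))) {
    drs_abort("score and truth must be finite and of equal length",
              "invalid_argument")
  }
  n_pos <- sum(truth); n_neg <- sum(!truth)
  if (n_pos == 0 || n_neg == 0) {
    drs_abort("both classes must be present", "invalid_argument")
  }
  ord <- order(score, decreasing = TRUE)
  s_sorted <- score[ord]; t_sorted <- truth[ord]
  # cumulative positives/negatives called positive at each distinct cut
  runs <- rle(s_sorted)
  thresholds <- c(Inf, runs$values)
  cut_idx <- cumsum(runs$lengths)
  tp <- c(0, cumsum(t_sorted)[cut_idx])
  fp <- c(0, cumsum(!t_sorted)[cut_idx])
  sens <- tp / n_pos
  spec <- 1 - fp / n_neg
  curve <- tibble::tibble(threshold = thresholds,
                          sensitivity = sens, specificity = spec)
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (sens[-1] + sens[-length(sens)]) / 2)
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.max(spec[best])]
  structure(
    list(curve = curve, auc = auc,
         youden_cutpoint = thresholds[best],
         youden_sens = sens[best], youden_spec = spec[best],
         youden_J = sens[best] + spec[best] - 1,
         n_pos = n_pos, n_neg = n_neg),
    class = "drs_roc")
}

#' Area under the ROC curve
#'
#' Trapezoidal area; equal to the probability that a random positive
#' outscores a random negative, counting ties one half.
#'
#' @param roc A `drs_roc`.
#' @return Numeric in \[0, 1\].
#' @export
auc <- function(roc) {
  stopifnot(inherits(roc, "drs_roc"))
  roc$auc
}

#' Youden-optimal operating point
#'
#' @param roc A `drs_roc`.
#' @return One-row tibble: `cutpoint`, `sensitivity`, `specificity`, `J`.
#' @export
youden_optimal <- function(roc) {
  stopifnot(inherits(roc, "drs_roc"))
  tibble::tibble(cutpoint = roc$youden_cutpoint,
                 sensitivity = roc$youden_sens,
                 specificity = roc$youden_spec,
                 J = roc$youden_J)
}

#' @export
tidy.drs_roc <- function(x, ...) x$curve

#' @export
glance.drs_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, cutpoint = x$youden_cutpoint,
                 sensitivity = x$youden_sens, specificity = x$youden_spec,
                 J = x$youden_J, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @export
print.drs_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f; Youden cutpoint %.3f (sens %.3f, spec %.3f, J %.3f); %d pos / %d neg\n",
              x$auc, x$youden_cutpoint, x$youden_sens, x$youden_spec,
              x$youden_J, x$n_pos, x$n_neg))
  invisible(x)
}

#' Pairwise performance report
#'
#' AUC, Youden-optimal sensitivity and specificity for every tissue pair,
#' in a lower-triangular orientation: for tissues in report order, the pair
#' (i, j) with j > i is scored with the row tissue `tissues[j]` as the
#' positive class against the column tissue `tissues[i]`.
#'
#' @param predictions Prediction tibble or `drs_loocv`.
#' @param tissues Tissue order; defaults to the classes of the `drs_loocv`
#'   or order of appearance.
#' @return A `drs_report` tibble: one row per pair with `positive`,
#'   `negative`, `auc`, `sensitivity`, `specificity`, `cutpoint`, `J`, `n`.
#' @export
report_matrix <- function(predictions, tissues = NULL) {
  if (inherits(predictions, "drs_loocv")) {
    tissues <- tissues %||% predictions$classes
    predictions <- predictions$predictions
  }
  tissues <- tissues %||% unique(predictions$tissue)
  if (length(tissues) < 2L) {
    drs_abort("need at least two tissues", "invalid_argument")
  }
  rows <- list()
  for (j in seq_along(tissues)) {
    for (i in seq_len(j - 1L)) {
      ps <- pairwise_score(predictions, positive = tissues[j],
                           negative = tissues[i])
      roc <- roc_curve(ps$score, ps$tissue, positive = tissues[j])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        positive = tissues[j], negative = tissues[i],
        auc = roc$auc, sensitivity = roc$youden_sens,
        specificity = roc$youden_spec, cutpoint = roc$youden_cutpoint,
        J = roc$youden_J, n = nrow(ps))
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "tissues") <- tissues
  class(out) <- unique(c("drs_report", class(out)))
  out
}

#' Lower-triangular matrix view of one report metric
#'
#' @param report A `drs_report`.
#' @param metric One of `"auc"`, `"sensitivity"`, `"specificity"`.
#' @return Tibble, rows = positive tissue, columns = negative tissue.
#' @export
report_wide <- function(report, metric = c("auc", "sensitivity", "specificity")) {
  metric <- match.arg(metric)
  report |>
    dplyr::select("positive", "negative", dplyr::all_of(metric)) |>
    tidyr::pivot_wider(names_from = "negative", values_from = dplyr::all_of(metric))
}
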