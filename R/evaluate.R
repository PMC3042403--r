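# Specimen-grouped leave-one-out cross-validation. Each fold holds out all
# repeated measurements of one physical specimen, preventing the optimism
# of repeated-measure leakage. Within every fold the full preprocessing and
# modelling chain (standardizer, PCA, component selection, LDA) is fitted
# on the training specimens only.

#' Leave-one-specimen-out folds
#'
#' One fold per distinct specimen: its test set is every observation of
#' that specimen, training is everything else. Folds are ordered by
#' specimen id.
#'
#' @param x Spectra tibble (or any tibble) with a `specimen_id` column.
#' @return Tibble with `fold`, `specimen_id`, and list-columns `test` /
#'   `train` of row indices.
#' @export
specimen_folds <- function(x) {
  if (!"specimen_id" %in% names(x)) {
    drs_abort("every observation needs a specimen_id", "invalid_argument")
  }
  ids <- sort(unique(x$specimen_id))
  all_idx <- seq_len(nrow(x))
  tibble::tibble(
    fold = seq_along(ids),
    specimen_id = ids,
    test = lapply(ids, function(id) all_idx[x$specimen_id == id]),
    train = lapply(ids, function(id) all_idx[x$specimen_id != id]))
}

#' Run grouped leave-one-out cross-validation
#'
#' Per fold: fit the wavelength standardizer on the training specimens,
#' standardize both halves, fit PCA on the training half, and classify with
#' LDA on a set of principal-component scores. Three protocols:
#'
#' * `mode = "adaptive"` — each fold selects its own components by pairwise
#'   Mann-Whitney U-tests ([select_pcs()]).
#' * `mode = "fixed"` — every fold uses `fixed_pcs`.
#' * `mode = "two_pass"` (default) — a first adaptive pass collects
#'   per-fold selections; their intersection ([consensus_pcs()]) is then
#'   used as the fixed set in a second pass. This is the protocol suited to
#'   a practical classifier, where per-fold adaptivity is not available.
#'
#' @param x Reflectance-stage spectra tibble on a common grid with
#'   `tissue` and `specimen_id` columns.
#' @param mode Protocol, see above.
#' @param fixed_pcs Integer component indices for `"fixed"` mode.
#' @param picks_per_pair Components per pairwise comparison (adaptive
#'   selection).
#' @param max_pcs Optional cap on the components computed and tested per
#'   fold.
#' @param priors Passed to [fit_lda()]. Defaults to `"equal"`: holding out
#'   one specimen leaves its class under-represented in training, so
#'   per-fold empirical frequencies would systematically penalize the
#'   held-out class; equal priors reflect the balanced acquisition design.
#' @param grouping `"specimen"` (grouped folds; default) or
#'   `"observation"` (naive spectrum-level LOOCV, provided to demonstrate
#'   the leakage bias grouped folds avoid).
#' @param fallback_consensus Passed to [consensus_pcs()].
#' @return A `drs_loocv`: `predictions` (one row per observation with
#'   posterior columns `p_<class>`, fold index and truth), `fold_selections`
#'   (adaptive/two-pass), `consensus`, `classes`, `mode`.
#' @export
run_loocv <- function(x, mode = c("two_pass", "adaptive", "fixed"),
                      fixed_pcs = NULL, picks_per_pair = 3, max_pcs = NULL,
                      priors = "equal", grouping = c("specimen", "observation"),
                      fallback_consensus = FALSE) {
  mode <- match.arg(mode)
  grouping <- match.arg(grouping)
  if (!all(c("tissue", "specimen_id") %in% names(x))) {
    drs_abort("dataset needs tissue and specimen_id columns", "invalid_argument")
  }
  stage <- spectra_stage(x)
  if (!stage %in% c("reflectance", "standardized")) {
    drs_abort(sprintf("expected a reflectance-stage dataset, got stage '%s'", stage),
              "invalid_argument")
  }
  if (mode == "fixed" && !length(fixed_pcs)) {
    drs_abort("mode = 'fixed' requires fixed_pcs", "invalid_argument")
  }
  m <- spectra_matrix(x)
  wl <- spectra_wavelengths(x)
  labels <- x$tissue
  classes <- unique(labels)
  folds <- if (grouping == "specimen") {
    specimen_folds(x)
  } else {
    tibble::tibble(fold = seq_len(nrow(x)),
                   specimen_id = x$specimen_id,
                   test = as.list(seq_len(nrow(x))),
                   train = lapply(seq_len(nrow(x)), function(i) setdiff(seq_len(nrow(x)), i)))
  }

  run_pass <- function(selection_mode, pcs_fixed, want_predictions) {
    selections <- vector("list", nrow(folds))
    preds <- vector("list", nrow(folds))
    for (f in seq_len(nrow(folds))) {
      tr <- folds$train[[f]]; te <- folds$test[[f]]
      if (!length(tr)) {
        drs_abort(sprintf("fold %d has an empty training set", f),
                  "insufficient_data")
      }
      stopifnot(!any(x$specimen_id[te] %in% x$specimen_id[tr]) ||
                  grouping == "observation")
      res <- tryCatch({
        mtr <- m[tr, , drop = FALSE]
        mu <- colMeans(mtr)
        sds <- apply(mtr, 2, sd)
        sds[sds < 1e-12] <- 1
        ztr <- sweep(sweep(mtr, 2, mu, "-"), 2, sds, "/")
        zte <- sweep(sweep(m[te, , drop = FALSE], 2, mu, "-"), 2, sds, "/")
        pca <- fit_pca(ztr, max_pcs = max_pcs)
        str_scores <- pca$scores
        sel <- NULL
        idx <- if (selection_mode == "adaptive") {
          sel <- select_pcs(str_scores, labels[tr], picks_per_pair = picks_per_pair)
          sel$selected
        } else {
          if (max(pcs_fixed) > pca$k) {
            drs_abort(sprintf("fixed component %d exceeds the %d available in this fold",
                              max(pcs_fixed), pca$k),
                      "invalid_argument")
          }
          as.integer(pcs_fixed)
        }
        pred <- if (want_predictions) {
          model <- fit_lda(str_scores[, idx, drop = FALSE], labels[tr],
                           priors = priors)
          ste <- pca_transform(pca, zte)[, idx, drop = FALSE]
          post <- predict_proba(model, ste)
          names(post) <- paste0("p_", names(post))
          dplyr::bind_cols(
            tibble::tibble(observation = te, tissue = labels[te],
                           specimen_id = x$specimen_id[te], fold = f),
            post)
        } else NULL
        list(pred = pred, sel = sel)
      }, drs_error = function(e) {
        drs_abort(sprintf("fold %d (specimen %s): %s", f, folds$specimen_id[f],
                          conditionMessage(e)),
                  class = sub("^drs_", "", class(e)[1]))
      })
      preds[[f]] <- res$pred
      selections[[f]] <- res$sel
    }
    list(selections = selections, predictions = dplyr::bind_rows(preds))
  }

  fold_selections <- NULL; consensus <- NULL
  if (mode == "adaptive") {
    pass <- run_pass("adaptive", NULL, want_predictions = TRUE)
    fold_selections <- pass$selections
    predictions <- pass$predictions
  } else if (mode == "fixed") {
    pass <- run_pass("fixed", fixed_pcs, want_predictions = TRUE)
    consensus <- sort(as.integer(fixed_pcs))
    predictions <- pass$predictions
  } else {
    pass1 <- run_pass("adaptive", NULL, want_predictions = FALSE)
    fold_selections <- pass1$selections
    consensus <- consensus_pcs(pass1$selections, fallback = fallback_consensus)
    predictions <- run_pass("fixed", consensus, want_predictions = TRUE)$predictions
  }
  predictions <- predictions[order(predictions$observation), ]
  structure(
    list(predictions = predictions, fold_selections = fold_selections,
         consensus = consensus, classes = classes, mode = mode,
         grouping = grouping, n_folds = nrow(folds)),
    class = "drs_loocv")
}

#' @export
tidy.drs_loocv <- function(x, ...) x$predictions

#' @export
glance.drs_loocv <- function(x, ...) {
  tibble::tibble(
    n_folds = x$n_folds, n_observations = nrow(x$predictions),
    mode = x$mode, grouping = x$grouping,
    n_consensus = length(x$consensus %||% integer()),
    consensus = paste(x$consensus %||% integer(), collapse = ","))
}

#' @export
print.drs_loocv <- function(x, ...) {
  cat(sprintf("Grouped LOOCV (%s, %s): %d folds, %d observations, %d classes\n",
              x$mode, x$grouping, x$n_folds, nrow(x$predictions),
              length(x$classes)))
  if (!is.null(x$consensus)) {
    cat(sprintf("  components used: {%s}\n", paste(x$consensus, collapse = ", ")))
  }
  invisible(x)
}
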