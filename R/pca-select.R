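# PCA of standardized spectra and Mann-Whitney-based selection of
# discriminative components: for every pairwise tissue comparison the
# components with the three lowest two-sided U-test p-values are picked;
# the union over pairs is the fold's selection, and the intersection across
# cross-validation folds is the consensus set used by the fixed protocol.

#' Principal component decomposition
#'
#' Components are eigenvectors of the sample covariance, ordered by
#' decreasing explained variance. Computed from the centered data matrix by
#' eigen-decomposition of the smaller of the `p x p` covariance or the
#' `n x n` Gram problem (via SVD), so folds with fewer observations than
#' wavelengths stay cheap. Sign convention: each loading column's
#' largest-magnitude element is made positive, making results reproducible
#' across platforms.
#'
#' @param x Spectra tibble (typically stage `"standardized"`) or numeric
#'   matrix, observations in rows.
#' @param max_pcs Optional cap on retained components (default
#'   `min(n - 1, p)`).
#' @return A `drs_pca` with `loadings` (p x k, orthonormal columns),
#'   `explained_fraction`, `center`, `scores` (fit-time scores), `k`, and
#'   the wavelength grid when the input was a spectra tibble.
#' @export
fit_pca <- function(x, max_pcs = NULL) {
  wl <- NULL
  if (is.data.frame(x)) {
    wl <- spectra_wavelengths(x)
    x <- spectra_matrix(x)
  }
  n <- nrow(x); p <- ncol(x)
  if (n < 2L) drs_abort("PCA needs at least 2 observations", "insufficient_data")
  k <- min(n - 1L, p)
  if (!is.null(max_pcs)) k <- min(k, as.integer(max_pcs))
  center <- colMeans(x)
  xc <- sweep(x, 2, center, "-")
  if (p <= n) {
    ee <- eigen(crossprod(xc) / (n - 1), symmetric = TRUE)
    values <- pmax(ee$values, 0)
    loadings <- ee$vectors[, seq_len(k), drop = FALSE]
    var_k <- values[seq_len(k)]
    total <- sum(values)
  } else {
    sv <- svd(xc, nu = 0, nv = k)
    values <- sv$d^2 / (n - 1)
    loadings <- sv$v
    var_k <- values[seq_len(k)]
    total <- sum(values)
  }
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) loadings[, j] <- -loadings[, j]
  }
  structure(
    list(loadings = loadings,
         explained_fraction = if (total > 0) var_k / total else rep(0, k),
         sdev = sqrt(var_k),
         center = center, k = k, n = n, p = p,
         wavelengths = wl,
         scores = xc %*% loadings),
    class = "drs_pca")
}

#' Project data onto a fitted PCA basis
#'
#' @param model A `drs_pca`.
#' @param x Spectra tibble or matrix with the model's `p` columns.
#' @return `n x k` score matrix.
#' @export
pca_transform <- function(model, x) {
  stopifnot(inherits(model, "drs_pca"))
  if (is.data.frame(x)) x <- spectra_matrix(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$p) {
    drs_abort(sprintf("expected %d columns, got %d", model$p, ncol(x)),
              "alignment_error")
  }
  sweep(x, 2, model$center, "-") %*% model$loadings
}

#' @export
tidy.drs_pca <- function(x, ...) {
  tibble::tibble(component = seq_len(x$k),
                 explained_fraction = x$explained_fraction,
                 cumulative = cumsum(x$explained_fraction))
}

#' @export
glance.drs_pca <- function(x, ...) {
  tibble::tibble(k = x$k, n = x$n, p = x$p,
                 explained_k = sum(x$explained_fraction))
}

#' Two-sided Mann-Whitney U-test p-value
#'
#' The two-sample rank test used to score each principal component's
#' discriminative power between a tissue pair. Midrank tie handling; exact
#' p by enumeration when the pooled sample has at most 10 tie-free values,
#' otherwise the tie-corrected normal approximation with continuity
#' correction (via [stats::wilcox.test()]).
#'
#' @param a,b Non-empty numeric samples.
#' @return Two-sided p-value in (0, 1].
#' @export
mann_whitney_p <- function(a, b) {
  if (!length(a) || !length(b) || !all(is.finite(c(a, b)))) {
    drs_abort("both samples must be non-empty and finite", "invalid_argument")
  }
  pooled <- c(a, b)
  exact <- (length(pooled) <= 10L) && !anyDuplicated(pooled)
  p <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
  if (!is.finite(p)) return(1)  # fully tied samples: no evidence either way
  min(1, p)
}

#' Select discriminative principal components by pairwise U-tests
#'
#' For every pair of classes, each component's scores are compared between
#' the two classes with a two-sided Mann-Whitney U-test, and the
#' `picks_per_pair` components with the lowest p-values are picked (ties
#' broken toward the lower component index, i.e. the higher-variance
#' component). The selection is the sorted union over pairs: with `c`
#' classes it has between `picks_per_pair` and
#' `picks_per_pair * c(c-1)/2` members.
#'
#' @param scores `n x k` score matrix (or `drs_pca`, whose fit-time scores
#'   are used).
#' @param labels Class label per observation, at least two classes.
#' @param picks_per_pair Components picked per pairwise comparison.
#' @return A `drs_pc_selection`: `pvalue_table` (long tibble: component,
#'   class_a, class_b, p_value), `per_pair_picks`, `selected`.
#' @export
select_pcs <- function(scores, labels, picks_per_pair = 3) {
  if (inherits(scores, "drs_pca")) scores <- scores$scores
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  if (length(labels) != nrow(scores)) {
    drs_abort("labels must have one entry per score row", "alignment_error")
  }
  classes <- unique(labels)
  if (length(classes) < 2L) {
    drs_abort("component selection needs at least two classes", "invalid_argument")
  }
  k <- ncol(scores)
  if (k < picks_per_pair) {
    drs_abort(sprintf("need at least picks_per_pair = %d components, have %d",
                      picks_per_pair, k),
              "invalid_argument")
  }
  pairs <- utils::combn(classes, 2)
  tabs <- vector("list", ncol(pairs))
  picks <- vector("list", ncol(pairs))
  for (q in seq_len(ncol(pairs))) {
    ia <- labels == pairs[1, q]
    ib <- labels == pairs[2, q]
    pv <- vapply(seq_len(k),
                 function(j) mann_whitney_p(scores[ia, j], scores[ib, j]),
                 numeric(1))
    tabs[[q]] <- tibble::tibble(component = seq_len(k),
                                class_a = pairs[1, q], class_b = pairs[2, q],
                                p_value = pv)
    picks[[q]] <- sort(order(pv, seq_len(k))[seq_len(picks_per_pair)])
  }
  names(picks) <- paste(pairs[1, ], pairs[2, ], sep = " vs ")
  structure(
    list(pvalue_table = dplyr::bind_rows(tabs),
         per_pair_picks = picks,
         selected = sort(unique(unlist(picks))),
         picks_per_pair = picks_per_pair,
         classes = classes),
    class = "drs_pc_selection")
}

#' @export
tidy.drs_pc_selection <- function(x, ...) x$pvalue_table

#' @export
glance.drs_pc_selection <- function(x, ...) {
  tibble::tibble(n_selected = length(x$selected),
                 n_pairs = length(x$per_pair_picks),
                 picks_per_pair = x$picks_per_pair)
}

#' @export
print.drs_pc_selection <- function(x, ...) {
  cat(sprintf("PC selection: %d component(s) {%s} from %d pairwise comparison(s)\n",
              length(x$selected), paste(x$selected, collapse = ", "),
              length(x$per_pair_picks)))
  invisible(x)
}

#' Consensus components across cross-validation folds
#'
#' The intersection of the per-fold selections, sorted ascending: the
#' components every fold agreed on, suitable for a fixed (non-adaptive)
#' classification protocol. An empty intersection is an error unless
#' `fallback = TRUE`, in which case components selected in at least half
#' of the folds are used instead (with a prominent warning).
#'
#' @param selections List of `drs_pc_selection`s or integer vectors.
#' @param fallback Use the >= 50 percent-frequency fallback on empty
#'   intersection.
#' @return Sorted integer vector of component indices.
#' @export
consensus_pcs <- function(selections, fallback = FALSE) {
  if (!length(selections)) {
    drs_abort("need at least one fold selection", "invalid_argument")
  }
  sets <- lapply(selections, function(s) {
    if (inherits(s, "drs_pc_selection")) s$selected else as.integer(s)
  })
  consensus <- sort(Reduce(intersect, sets))
  if (length(consensus)) return(consensus)
  if (!fallback) {
    drs_abort("no component was selected in every fold (empty consensus)",
              "empty_consensus")
  }
  freq <- table(unlist(lapply(sets, unique)))
  keep <- sort(as.integer(names(freq)[freq >= length(sets) / 2]))
  if (!length(keep)) {
    drs_abort("empty consensus even under the 50%-frequency fallback",
              "empty_consensus")
  }
  drs_warn(sprintf("empty consensus; falling back to components selected in >= 50%% of folds: {%s}",
                   paste(keep, collapse = ", ")),
           "consensus_fallback")
  keep
}
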