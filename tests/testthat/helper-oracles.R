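# Independent brute-force oracles used to pin down expected values.

# Exact two-sided Mann-Whitney p-value by exhaustive enumeration of all
# C(m+n, m) assignments of the pooled (tie-free) sample to group A.
enumerate_mw_p <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  m <- length(a)
  ranks <- rank(pooled)
  u_obs <- sum(ranks[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(length(pooled), m)
  u_all <- apply(combos, 2, function(idx) sum(ranks[idx]) - m * (m + 1) / 2)
  mu <- m * length(b) / 2
  # two-sided: total probability of |U - mu| at least as extreme
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

# AUC as the concordant-pair fraction with ties counted one half.
paircount_auc <- function(score, truth) {
  pos <- score[truth]; neg <- score[!truth]
  grid <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(grid)
}

# Closed-form two-class 1-D normal posterior with shared variance.
posterior_1d <- function(z, mu1, mu2, sigma2, prior1 = 0.5) {
  d1 <- prior1 * exp(-(z - mu1)^2 / (2 * sigma2))
  d2 <- (1 - prior1) * exp(-(z - mu2)^2 / (2 * sigma2))
  d1 / (d1 + d2)
}

# Small reflectance-stage dataset for pipeline-level tests: the named
# scenario at reduced spots/repeats, preprocessed onto a reduced canonical
# grid so cross-validation stays fast.
small_reflectance_dataset <- function(name = "paperlike", seed = 1L,
                                      samples = 12L, spots = 2L, repeats = 3L,
                                      target_points = 1150,
                                      sigma_specimen = NULL) {
  sc <- scenario(name, seed = seed)
  sc$design$samples_per_tissue <- as.integer(samples)
  sc$design$spots_per_sample <- as.integer(spots)
  sc$design$repeats_per_spot <- as.integer(repeats)
  if (!is.null(sigma_specimen)) sc$design$sigma_specimen <- sigma_specimen
  sim <- simulate_dataset(sc$design, sc$instrument)
  compute_reflectance(sim$spectra, sim$reference) |>
    crop_spectra(target_points = target_points)
}
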