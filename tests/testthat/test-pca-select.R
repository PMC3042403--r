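test_that("rank-1 data yields a single dominant component", {
  set.seed(1)
  direction <- rnorm(6)
  x <- outer(rnorm(20), direction)
  pca <- fit_pca(x)
  expect_equal(pca$explained_fraction[1], 1, tolerance = 1e-10)
})

test_that("loadings are orthonormal and the 2x2 case matches the closed form", {
  set.seed(2)
  x <- matrix(rnorm(40 * 7), 40)
  pca <- fit_pca(x)
  gram <- crossprod(pca$loadings)
  expect_equal(gram, diag(ncol(x)), tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(pca$explained_fraction) <= 1e-12))
  expect_lte(sum(pca$explained_fraction), 1 + 1e-8)

  # closed-form eigenvalues of a 2x2 covariance
  x2 <- matrix(rnorm(30 * 2), 30)
  s <- stats::cov(x2)
  tr <- s[1, 1] + s[2, 2]
  det_ <- s[1, 1] * s[2, 2] - s[1, 2]^2
  eigs <- c((tr + sqrt(tr^2 - 4 * det_)) / 2, (tr - sqrt(tr^2 - 4 * det_)) / 2)
  pca2 <- fit_pca(x2)
  expect_equal(pca2$explained_fraction, eigs / sum(eigs), tolerance = 1e-10)

  # cross-check scores and variance fractions against prcomp
  pr <- stats::prcomp(x2, center = TRUE, scale. = FALSE)
  expect_equal(abs(pca2$scores), abs(pr$x), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("transform is linear, reproduces fit scores, and reconstructs", {
  set.seed(3)
  x <- matrix(rnorm(25 * 6), 25)
  pca <- fit_pca(x)
  expect_equal(pca_transform(pca, x), pca$scores, tolerance = 1e-12)

  a <- rnorm(6); b <- rnorm(6)
  centered_sum <- pca_transform(pca, rbind(a + b + pca$center))
  parts <- pca_transform(pca, rbind(a + pca$center)) +
    pca_transform(pca, rbind(b + pca$center)) - 0  # linearity about the center
  expect_equal(centered_sum, parts, tolerance = 1e-10)

  # reconstruction error non-increasing in k; exact at full rank
  errs <- vapply(1:6, function(k) {
    xhat <- pca$scores[, 1:k, drop = FALSE] %*% t(pca$loadings[, 1:k, drop = FALSE])
    sum((sweep(x, 2, pca$center) - xhat)^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
  expect_lt(errs[6], 1e-16 * sum(x^2) + 1e-12)

  expect_error(pca_transform(pca, matrix(0, 2, 5)), class = "drs_alignment_error")
  expect_error(fit_pca(x[1, , drop = FALSE]), class = "drs_insufficient_data")
})

test_that("the wide-matrix (n < p) SVD path agrees with prcomp", {
  set.seed(4)
  x <- matrix(rnorm(8 * 20), 8)
  wide <- fit_pca(x)
  expect_equal(wide$k, 7)
  pr <- stats::prcomp(x)
  expect_equal(wide$explained_fraction,
               (pr$sdev^2 / sum(pr$sdev^2))[1:7], tolerance = 1e-10)
  expect_equal(abs(wide$scores), abs(pr$x[, 1:7]), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("Mann-Whitney p-values match exhaustive enumeration and are symmetric", {
  expect_equal(mann_whitney_p(c(1, 2, 3), c(4, 5, 6)), 0.1, tolerance = 1e-12)

  set.seed(5)
  for (rep in 1:40) {
    vals <- sample(1:10000, 10)
    a <- vals[1:5]; b <- vals[6:10]
    p_impl <- mann_whitney_p(a, b)
    p_oracle <- enumerate_mw_p(a, b)
    expect_lt(abs(p_impl - p_oracle), 1e-12)
    expect_equal(mann_whitney_p(b, a), p_impl, tolerance = 1e-12)
  }

  # large tied samples: approximate branch, sane and symmetric
  set.seed(6)
  a <- round(rnorm(40), 1); b <- round(rnorm(35, 0.5), 1)
  p <- mann_whitney_p(a, b)
  expect_true(p > 0 && p <= 1)
  expect_equal(mann_whitney_p(b, a), p, tolerance = 1e-12)
  expect_equal(p, stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-12)

  expect_equal(mann_whitney_p(c(2, 2, 2), c(2, 2, 2)), 1)
  expect_gt(mann_whitney_p(c(1, 2, 3, 4), c(1, 2, 3, 4)), 0.9)
  expect_error(mann_whitney_p(numeric(0), 1), class = "drs_invalid_argument")
})

test_that("approximate p stays close to the exact p for moderate samples", {
  set.seed(7)
  for (rep in 1:25) {
    vals <- sample(1:10^6, 10)
    a <- vals[1:5]; b <- vals[6:10]
    exact <- enumerate_mw_p(a, b)
    approx <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
    expect_lt(abs(approx - exact), 0.02)
  }
})

test_that("selection picks the lowest p-values per pair and unions over pairs", {
  set.seed(8)
  n <- 60
  labels <- rep(c("a", "b"), each = n / 2)
  scores <- matrix(rnorm(n * 6), n)
  scores[labels == "b", 2] <- scores[labels == "b", 2] + 3
  sel <- select_pcs(scores, labels)
  expect_length(sel$selected, 3)           # two classes: exactly 3
  expect_true(2 %in% sel$selected)

  # four classes with disjoint best-3 sets per pair -> 18 selected: each
  # pair gets a 3-column block where its two members sit at +/-2 (strong,
  # near-complete separation) while every other class sits at 0 (weaker,
  # overlapping separation), so the block is that pair's best 3
  labs4 <- rep(c("a", "b", "c", "d"), each = 20)
  big <- matrix(rnorm(80 * 18), 80)
  pairs <- utils::combn(unique(labs4), 2)
  for (q in seq_len(ncol(pairs))) {
    cols <- (q - 1) * 3 + 1:3
    big[labs4 == pairs[1, q], cols] <- big[labs4 == pairs[1, q], cols] + 2
    big[labs4 == pairs[2, q], cols] <- big[labs4 == pairs[2, q], cols] - 2
  }
  sel18 <- select_pcs(big, labs4)
  expect_length(sel18$selected, 18)
  expect_equal(sel18$per_pair_picks[["a vs b"]], 1:3)

  # identical best columns for every pair -> exactly {1,2,3}
  shared <- matrix(rnorm(80 * 10, sd = 0.01), 80)
  shift <- as.numeric(factor(labs4))
  shared[, 1] <- shared[, 1] + 50 * shift
  shared[, 2] <- shared[, 2] - 30 * shift
  shared[, 3] <- shared[, 3] + 20 * shift^2
  expect_equal(select_pcs(shared, labs4)$selected, c(1L, 2L, 3L))

  expect_error(select_pcs(scores, rep("a", n)), class = "drs_invalid_argument")
  expect_error(select_pcs(scores[, 1:2], labels), class = "drs_invalid_argument")
})

test_that("selection size is always between 3 and 18 for four classes", {
  set.seed(9)
  labs <- rep(c("a", "b", "c", "d"), each = 15)
  for (rep in 1:20) {
    scores <- matrix(rnorm(60 * 25), 60)
    n_sel <- length(select_pcs(scores, labs)$selected)
    expect_gte(n_sel, 3)
    expect_lte(n_sel, 18)
  }
})

test_that("p-value ties break toward the lower component index", {
  # columns 2 and 3 are identical (equal p-values); with one slot the
  # lower index must win
  set.seed(10)
  labels <- rep(c("a", "b"), each = 6)
  base <- c(rnorm(6), rnorm(6, 8))
  scores <- cbind(rnorm(12), base, base)
  sel <- select_pcs(scores, labels, picks_per_pair = 1)
  expect_equal(sel$per_pair_picks[[1]], 2L)
  # with two slots both tied columns are taken, in index order
  sel2 <- select_pcs(scores, labels, picks_per_pair = 2)
  expect_equal(sel2$per_pair_picks[[1]], c(2L, 3L))
})

test_that("consensus is the sorted intersection across folds", {
  expect_equal(consensus_pcs(list(c(1, 2, 4, 5, 9, 11), c(1, 2, 4, 5, 9, 12))),
               c(1, 2, 4, 5, 9))
  expect_equal(consensus_pcs(list(c(3, 1, 7))), c(1, 3, 7))
  expect_error(consensus_pcs(list(1:3, 4:6)), class = "drs_empty_consensus")
})

test_that("consensus fallback keeps components selected in at least half the folds", {
  expect_warning(
    fb <- consensus_pcs(list(c(1, 2), c(2, 3), c(2, 4), c(1, 5)),
                        fallback = TRUE),
    class = "drs_consensus_fallback")
  expect_equal(fb, c(1L, 2L))
})
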