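test_that("specimen folds partition the data with no leakage", {
  x <- small_reflectance_dataset("separable", samples = 3, spots = 2,
                                 repeats = 2, target_points = 50)
  folds <- specimen_folds(x)
  expect_equal(nrow(folds), 12)  # 4 tissues x 3 samples
  test_union <- sort(unlist(folds$test))
  expect_equal(test_union, seq_len(nrow(x)))
  expect_equal(sum(lengths(folds$test)), nrow(x))  # disjoint + exhaustive
  for (f in seq_len(nrow(folds))) {
    test_specs <- unique(x$specimen_id[folds$test[[f]]])
    train_specs <- unique(x$specimen_id[folds$train[[f]]])
    expect_length(test_specs, 1)
    expect_false(test_specs %in% train_specs)
    expect_length(folds$test[[f]], 4)  # 2 spots x 2 repeats
  }
})

test_that("48-specimen designs yield 48 folds", {
  x <- small_reflectance_dataset("separable", samples = 12, spots = 1,
                                 repeats = 1, target_points = 30)
  expect_equal(nrow(specimen_folds(x)), 48)
})

test_that("every observation is predicted exactly once, order-invariantly", {
  x <- small_reflectance_dataset("separable", samples = 3, spots = 2,
                                 repeats = 2, target_points = 80)
  cv <- run_loocv(x, mode = "adaptive", max_pcs = 15)
  expect_equal(sort(cv$predictions$observation), seq_len(nrow(x)))
  expect_equal(cv$n_folds, 12)
  probs <- as.matrix(cv$predictions[paste0("p_", cv$classes)])
  expect_equal(rowSums(probs), rep(1, nrow(x)), tolerance = 1e-10)

  # shuffling the rows changes no per-observation prediction
  perm <- sample(nrow(x))
  xs <- drspectra:::set_stage(x[perm, ], "reflectance")
  cvs <- run_loocv(xs, mode = "adaptive", max_pcs = 15)
  reordered <- cvs$predictions[order(perm[cvs$predictions$observation]), ]
  expect_equal(as.matrix(reordered[paste0("p_", cv$classes)]), probs,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("fixed mode uses the requested components in every fold", {
  x <- small_reflectance_dataset("separable", samples = 3, spots = 2,
                                 repeats = 2, target_points = 80)
  cv <- run_loocv(x, mode = "fixed", fixed_pcs = c(1, 2, 4, 5, 9), max_pcs = 15)
  expect_equal(cv$consensus, c(1L, 2L, 4L, 5L, 9L))
  expect_error(run_loocv(x, mode = "fixed"), class = "drs_invalid_argument")
  expect_error(run_loocv(x, mode = "fixed", fixed_pcs = 500, max_pcs = 15),
               "fold 1", class = "drs_invalid_argument")
})

test_that("two-pass consensus is the intersection of per-fold selections", {
  x <- small_reflectance_dataset("paperlike", samples = 4, spots = 2,
                                 repeats = 2, target_points = 120)
  cv <- run_loocv(x, mode = "two_pass", max_pcs = 20)
  sets <- lapply(cv$fold_selections, function(s) s$selected)
  expect_equal(cv$consensus, sort(Reduce(intersect, sets)))
  expect_true(all(vapply(sets, function(s) length(s) >= 3 && length(s) <= 18,
                         logical(1))))
})

test_that("pairwise scores renormalize the two-class posterior", {
  preds <- tibble::tibble(
    observation = 1:3, tissue = c("a", "b", "a"),
    p_a = c(0.2, 0.1, 0.9), p_b = c(0.2, 0.1, 0.05), p_c = c(0.6, 0.8, 0.05))
  ps <- pairwise_score(preds, "a", "b")
  expect_equal(ps$score, c(0.5, 0.5, 0.9 / 0.95))
  # rescaling the third class's mass changes nothing
  preds2 <- preds
  preds2$p_c <- preds2$p_c * 0.1
  expect_equal(pairwise_score(preds2, "a", "b")$score, ps$score)
  expect_error(pairwise_score(preds, "a", "zz"), class = "drs_invalid_argument")
})

test_that("ROC curve endpoints, ties and symmetries behave", {
  sep <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(sep$auc, 1)
  expect_true(any(sep$curve$sensitivity == 1 & sep$curve$specificity == 1))
  expect_equal(youden_optimal(sep)$J, 1)

  tied <- roc_curve(rep(0.5, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(tied$auc, 0.5)
  expect_equal(tied$youden_J, 0)

  set.seed(6)
  sc <- runif(30); tr <- sample(c(TRUE, FALSE), 30, replace = TRUE)
  a <- roc_curve(sc, tr)
  b <- roc_curve(-sc, !tr)
  expect_equal(a$auc, b$auc, tolerance = 1e-12)

  expect_error(roc_curve(sc, rep(TRUE, 30)), class = "drs_invalid_argument")
  # sensitivity is non-increasing as the threshold rises
  expect_true(all(diff(a$curve$sensitivity) >= 0))  # curve stored falling-threshold
  expect_equal(a$curve$threshold[1], Inf)
})

test_that("trapezoidal AUC equals the concordant-pair fraction", {
  expect_equal(roc_curve(c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2),
                         c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))$auc,
               8 / 9, tolerance = 1e-12)
  set.seed(7)
  for (rep in 1:50) {
    n <- sample(4:20, 1)
    sc <- round(runif(n), sample(1:3, 1))  # induce ties
    tr <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    expect_equal(roc_curve(sc, tr)$auc, paircount_auc(sc, tr),
                 tolerance = 1e-12)
  }
})

test_that("Youden maximization matches a brute-force threshold scan", {
  set.seed(8)
  for (rep in 1:20) {
    n <- sample(6:25, 1)
    sc <- round(runif(n), 2)
    tr <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    roc <- roc_curve(sc, tr)
    brute <- vapply(c(Inf, sort(unique(sc), decreasing = TRUE)), function(th) {
      pred <- sc >= th
      sens <- sum(pred & tr) / sum(tr)
      spec <- sum(!pred & !tr) / sum(!tr)
      sens + spec - 1
    }, numeric(1))
    expect_equal(roc$youden_J, max(brute), tolerance = 1e-12)
    expect_equal(roc$youden_J, roc$youden_sens + roc$youden_spec - 1)
  }
})

test_that("Youden ties break toward higher specificity", {
  # two thresholds reach J = 0.5: cutting above 0.6 (sens .5, spec 1) and
  # above 0.4 (sens 1, spec .5); the high-specificity cut must win
  roc <- roc_curve(c(0.7, 0.5, 0.6, 0.4), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(roc$youden_spec, 1)
  expect_equal(roc$youden_sens, 0.5)
})

test_that("report covers all pairs in row-positive orientation", {
  x <- small_reflectance_dataset("separable", samples = 3, spots = 2,
                                 repeats = 2, target_points = 80)
  cv <- run_loocv(x, max_pcs = 15)
  rep4 <- report_matrix(cv)
  expect_equal(nrow(rep4), 6)
  expect_true(all(rep4$auc >= 0.99))  # separable scenario by construction
  expect_equal(attr(rep4, "tissues"), cv$classes)
  wide <- report_wide(rep4, "auc")
  expect_equal(nrow(wide), 3)

  two <- report_matrix(cv$predictions[cv$predictions$tissue %in%
                                        cv$classes[1:2], ])
  expect_equal(nrow(two), 1)
})

test_that("ROC agrees with pROC on cross-validated scores", {
  skip_if_not_installed("pROC")
  x <- small_reflectance_dataset("paperlike", samples = 3, spots = 2,
                                 repeats = 2, target_points = 80)
  cv <- run_loocv(x, max_pcs = 15)
  ps <- pairwise_score(cv, "nerve", "cortical_bone")
  mine <- roc_curve(ps$score, ps$tissue, positive = "nerve")
  ref <- pROC::roc(ps$tissue == "nerve", ps$score, quiet = TRUE, direction = "<")
  expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
})
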