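test_that("confusion metrics match hand-computed values", {
  cm <- matrix(c(50, 5, 5, 40), 2, byrow = TRUE,
               dimnames = list(c("pos", "neg"), c("pos", "neg")))
  m <- confusion_metrics(cm)
  expect_equal(m[["acc"]], 90)
  expect_equal(m[["sen"]], 50 / 55 * 100)
  expect_equal(m[["spe"]], 40 / 45 * 100)

  perfect <- diag(c(10, 20, 30))
  dimnames(perfect) <- list(letters[1:3], letters[1:3])
  expect_equal(unname(confusion_metrics(perfect)), c(100, 100, 100))

  cm4 <- rbind(c(10, 0, 0, 0), c(0, 10, 0, 0), c(0, 0, 5, 5),
               c(0, 0, 0, 10))
  dimnames(cm4) <- list(letters[1:4], letters[1:4])
  m4 <- confusion_metrics(cm4)
  expect_equal(m4[["acc"]], 87.5)
  expect_equal(m4[["sen"]], (100 + 100 + 50 + 100) / 4)
  # one-vs-rest specificity oracle by brute force over the 4 binary tables
  spe_ovr <- vapply(1:4, function(k) {
    tp <- cm4[k, k]; fn <- sum(cm4[k, ]) - tp; fp <- sum(cm4[, k]) - tp
    tn <- sum(cm4) - tp - fn - fp
    tn / (tn + fp) * 100
  }, numeric(1))
  expect_equal(m4[["spe"]], mean(spe_ovr))

  # class absent from the test set: excluded from macro SEN with a warning
  cm_empty <- rbind(c(5, 0, 0), c(0, 5, 0), c(0, 0, 0))
  dimnames(cm_empty) <- list(letters[1:3], letters[1:3])
  expect_warning(me <- confusion_metrics(cm_empty), "absent")
  expect_equal(me[["sen"]], 100)
})

test_that("stratified folds partition the data with balanced classes", {
  labels <- rep(c("a", "b", "c", "d"), times = c(13, 10, 17, 10))
  folds <- stratified_folds(labels, 5, seed = 3)
  expect_identical(sort(unique(folds)), 1:5)
  for (cl in unique(labels)) {
    counts <- table(folds[labels == cl])
    expect_lte(max(counts) - min(counts), 1)
  }
  expect_error(stratified_folds(rep(c("a", "b"), c(3, 50)), 5), "smaller than k")
})

test_that("cross-validation partitions each repeat and is seed-deterministic", {
  d <- gaussian_clouds(n_per_class = 25, p = 6, sep = 3)
  fm <- feature_matrix(d$x, d$y)
  r <- cross_validate(fm, classifier_spec("lda"), k = 5, repeats = 1,
                      seed = 7)
  totals <- vapply(r$confusions[[1]], sum, numeric(1))
  expect_length(totals, 5L)
  expect_equal(sum(totals), 50)
  r2 <- cross_validate(fm, classifier_spec("lda"), k = 5, repeats = 1,
                       seed = 7)
  expect_equal(r$fold_metrics, r2$fold_metrics)
  expect_equal(r$confusions, r2$confusions)
  r3 <- cross_validate(fm, classifier_spec("lda"), k = 5, repeats = 1,
                       seed = 8)
  expect_false(identical(r$confusions, r3$confusions))
})

test_that("degenerate subspace ensemble equals plain LDA and MASS::lda", {
  d <- gaussian_clouds(n_per_class = 40, p = 8, sep = 5)
  m_ens <- subspace_discriminant_fit(d$x, d$y, n_learners = 1,
                                     subspace_dim = ncol(d$x), seed = 2,
                                     reg = 1e-9)
  m_lda <- reg_lda_fit(d$x, d$y, reg = 1e-9)
  expect_identical(subspace_discriminant_predict(m_ens, d$x)$class,
                   reg_lda_predict(m_lda, d$x)$class)
  # independent oracle: MASS::lda on the same well-conditioned data
  mass_fit <- MASS::lda(d$x, grouping = factor(d$y))
  mass_pred <- as.character(predict(mass_fit, d$x)$class)
  expect_identical(reg_lda_predict(m_lda, d$x)$class, mass_pred)
})

test_that("subspace discriminant separates well-separated clouds", {
  d <- gaussian_clouds(n_per_class = 100, p = 10, sep = 8, seed = 12)
  m <- subspace_discriminant_fit(d$x, d$y, n_learners = 30, subspace_dim = 5,
                                 seed = 3)
  pred <- subspace_discriminant_predict(m, d$x)$class
  expect_gte(mean(pred == d$y), 0.99)
  # reproducibility of the stochastic subset draws
  m2 <- subspace_discriminant_fit(d$x, d$y, n_learners = 30, subspace_dim = 5,
                                  seed = 3)
  expect_identical(m$subsets, m2$subsets)
})

test_that("shuffled labels give chance-level CV accuracy", {
  set.seed(71)
  x <- matrix(rnorm(120 * 10), 120, dimnames = list(NULL, paste0("f", 1:10)))
  y <- sample(rep(c("a", "b"), each = 60))
  fm <- feature_matrix(x, y)
  for (fam in list(classifier_spec("ensemble_subspace_discriminant",
                                   n_learners = 10),
                   classifier_spec("knn", "medium"),
                   classifier_spec("tree", "medium"))) {
    r <- cross_validate(fm, fam, k = 5, repeats = 1, seed = 5)
    # CV accuracy on pure noise sits near 50% but is not binomial: folds are
    # correlated and flexible learners trained on noise are systematically a
    # little below chance, so allow a wider symmetric band
    expect_gt(r$acc, 35)
    expect_lt(r$acc, 65)
  }
})

test_that("every classifier family fits and predicts on separable data", {
  d <- gaussian_clouds(n_per_class = 30, p = 6, sep = 6, seed = 9)
  for (spec in classifier_grid(binary = TRUE)) {
    if (spec$preset == "coarse" && spec$family == "knn") next  # k > n
    model <- fit_classifier(spec, d$x, d$y, seed = 4)
    pred <- predict(model, d$x)
    expect_gte(mean(pred == d$y), 0.8, label = spec$id)
  }
})

test_that("in-package Euclidean k-NN agrees with class::knn", {
  d <- gaussian_clouds(n_per_class = 30, p = 5, sep = 2, seed = 14)
  set.seed(20)
  test_x <- matrix(rnorm(40 * 5), 40, dimnames = list(NULL, paste0("f", 1:5)))
  mine <- knn_predict(knn_fit(d$x, d$y, k = 1), test_x)
  ref <- as.character(class::knn(d$x, test_x, factor(d$y), k = 1))
  expect_identical(mine, ref)
})

test_that("logistic regression refuses more than two classes", {
  set.seed(77)
  x <- matrix(rnorm(30 * 4), 30, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rep(c("a", "b", "c"), each = 10)
  expect_error(fit_classifier(classifier_spec("logistic"), x, y),
               "2 classes")
})
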