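test_that("PCA on coplanar data explains all variance with two components", {
  set.seed(1)
  u <- rnorm(60); v <- rnorm(60)
  d <- tibble::tibble(SM = u + v, B = u - v, LS = 0.5 * u + 2 * v)
  pca <- pca_project(d)
  expect_equal(pca$variance_explained, 1.0, tolerance = 1e-10)
  expect_equal(dim(pca$loadings), c(3L, 3L))
})

test_that("PCA on an isotropic cloud explains about two thirds", {
  set.seed(2)
  d <- tibble::tibble(SM = rnorm(4000), B = rnorm(4000), LS = rnorm(4000))
  pca <- pca_project(d)
  expect_equal(pca$variance_explained, 2 / 3, tolerance = 0.04)
})

test_that("PCA signs are fixed and zero-variance columns rejected", {
  d <- simulate_descriptors("day", seed = 6)
  pca <- pca_project(d)
  for (k in 1:2) {
    load <- pca$loadings[, k]
    expect_gt(load[which.max(abs(load))], 0)
  }
  d_bad <- d; d_bad$B <- 1
  expect_error(pca_project(d_bad), class = "mfspectra_error_input")
})

test_that("the calibrated cohort concentrates on two components", {
  pca <- pca_project(simulate_descriptors("day", seed = 10))
  expect_gt(pca$variance_explained, 0.9)
})

test_that("rank-based AUC matches hand counts and handles ties", {
  # positives {0.9, 0.6}, negatives {0.8, 0.5}: 3 of 4 concordant pairs
  expect_equal(auc_rank(c(0.9, 0.6, 0.8, 0.5),
                        c("pos", "pos", "neg", "neg"), positive = "pos"), 0.75)
  # a tie counts one half
  expect_equal(auc_rank(c(0.7, 0.7), c("pos", "neg"), positive = "pos"), 0.5)
  expect_equal(auc_rank(c(1, 0), c("pos", "neg"), positive = "pos"), 1)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(3)
  for (rep in 1:10) {
    sc <- rnorm(40)
    y <- sample(c("a", "b"), 40, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(y)) < 2) next
    a1 <- auc_rank(sc, y, positive = "b")
    expect_equal(auc_rank(exp(sc), y, positive = "b"), a1, tolerance = 1e-12)
    expect_equal(auc_rank(atan(sc / 3) * 5 + 2, y, positive = "b"), a1,
                 tolerance = 1e-12)
  }
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(4)
  sc <- c(rnorm(30, 1), rnorm(40))
  y <- rep(c("pos", "neg"), c(30, 40))
  expect_equal(auc_rank(sc, y, positive = "pos"),
               as.numeric(pROC::auc(pROC::roc(y, sc, levels = c("neg", "pos"),
                                              direction = "<", quiet = TRUE))),
               tolerance = 1e-12)
})

sep_scores <- function(n = 30) {
  tibble::tibble(
    PC1 = c(rnorm(n, -4, 0.3), rnorm(n, 4, 0.3)),
    PC2 = rnorm(2 * n, 0, 0.3),
    group = factor(rep(c("High", "Low"), each = n)))
}

test_that("perfectly separated clusters give AUC 1 and error 0 everywhere", {
  ev <- evaluate_classifiers(sep_scores(), replications = 2, seed = 1)
  expect_equal(nrow(ev$table), 7L)
  expect_true(all(ev$table$auc_all_data == 1))
  expect_true(all(ev$table$error_all_data == 0))
  expect_true(all(ev$table$auc_cv_mean > 0.99))
  expect_true(all(ev$table$error_cv_mean < 0.01))
})

test_that("shuffled labels give chance-level cross-validated AUC", {
  set.seed(5)
  d <- simulate_descriptors("day", seed = 12)
  d$group <- sample(d$group)
  ev <- evaluate_classifiers(tidy(pca_project(d)), replications = 5, seed = 2)
  m <- ev$table$auc_cv_mean
  expect_true(all(abs(m - 0.5) < 3 / sqrt(nrow(d))))
})

test_that("resubstitution AUC is optimistic relative to cross-validation", {
  d <- simulate_descriptors("day", seed = 13)
  ev <- evaluate_classifiers(tidy(pca_project(d)), replications = 10, seed = 3)
  expect_gt(mean(ev$table$auc_all_data - ev$table$auc_cv_mean), 0)
  expect_true(all(ev$table$auc_all_data >= ev$table$auc_cv_mean - 0.03))
})

test_that("the calibrated cohort is discriminable by LDA and the linear margin classifier", {
  d <- simulate_descriptors("day", seed = 14)
  ev <- evaluate_classifiers(tidy(pca_project(d)), replications = 10, seed = 4)
  tab <- ev$table
  expect_gt(tab$auc_cv_mean[tab$classifier == "lda"], 0.85)
  expect_gt(tab$auc_cv_mean[tab$classifier == "svm_linear"], 0.85)
})

test_that("depletion and repletion are indiscriminate within a group", {
  d <- simulate_descriptors("day", seed = 15)
  d_low <- d[d$group == "Low", ]
  sc <- tidy(pca_project(d_low))
  ev <- evaluate_classifiers(sc, label = "period", replications = 5, seed = 5)
  expect_lt(max(ev$table$auc_cv_mean), 0.5 + 3 / sqrt(nrow(d_low)))
})

test_that("fold constraints and degenerate labels are rejected", {
  sc <- sep_scores(6)
  expect_error(evaluate_classifiers(sc, folds = 8, replications = 1, seed = 1),
               class = "mfspectra_error_input")
  sc$group <- factor("High", levels = c("High", "Low"))
  expect_error(evaluate_classifiers(sc, replications = 1, seed = 1),
               class = "mfspectra_error_input")
})
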