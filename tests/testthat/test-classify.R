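# Classification: stratified splitting, feature selection, PLS-DA
# training and evaluation, model comparison, leak-freedom.

test_that("stratified splitting reproduces the 129/32 partition and is disjoint", {
  labels <- factor(rep(c("CN", "sMCI", "cMCI", "AD"), times = c(46, 48, 27, 40)))
  sp <- split_cohort(labels, test_fraction = 0.2, seed = 4)
  expect_length(sp$test, 32)
  expect_length(sp$train, 129)
  expect_identical(sort(c(sp$train, sp$test)), seq_along(labels))
  expect_length(intersect(sp$train, sp$test), 0)
  # class proportions approximately preserved (largest-remainder quotas)
  cnt <- table(labels[sp$test])
  expect_equal(as.numeric(cnt[c("CN", "sMCI", "cMCI", "AD")]), c(9, 10, 5, 8))
  expect_identical(split_cohort(labels, 0.2, seed = 4), sp)
  expect_false(identical(split_cohort(labels, 0.2, seed = 5), sp))
  expect_error(split_cohort(factor(c("a", "a", "b")), 0.2, 1), ">= 5")
})

test_that("full-mode features are all upper-triangle pairs", {
  cc <- small_cohort(seed = 3, n_nodes = 12, groups = c(CN = 6, AD = 6))
  fs <- select_features(cc, "full")
  expect_identical(nrow(fs$edges), 66L)
  cc90 <- list(connectomes = list(S1 = random_connectome(90, 1)),
               cohort = data.frame())
  class(cc90) <- "connectome_cohort"
  expect_identical(nrow(select_features(cc90, "full")$edges), 4005L)
})

test_that("key-mode features are deduplicated training-side top-k unions", {
  cc <- small_cohort(seed = 7, effect = 3, n_nodes = 16,
                     groups = c(CN = 10, cMCI = 10), seeds = c(3, 8))
  fs <- select_features(cc, "key", B = 99, B_delta = 50, seed_p = 0.011,
                        k = 5, fallback_s = 2, seed = 2)
  expect_s3_class(fs$provenance, "data.frame")
  expect_false(any(duplicated(fs$edges)))
  expect_true(all(fs$edges[, 1] < fs$edges[, 2]))
  expect_lte(nrow(fs$edges), nrow(fs$provenance))
})

test_that("feature selection never touches held-out subjects", {
  cc <- small_cohort(seed = 9, effect = 2, n_nodes = 14,
                     groups = c(CN = 12, AD = 12), seeds = 4)
  sp <- split_cohort(cc$cohort$group, 0.25, seed = 1)
  tr <- mdmrnet:::subset_subjects(cc, sp$train)
  fs1 <- select_features(tr, "key", B = 99, B_delta = 50, fallback_s = 2, seed = 5)
  # poison the test subjects: selected features must not change
  poisoned <- cc
  for (i in sp$test) {
    id <- as.character(cc$cohort$subject_id[i])
    poisoned$connectomes[[id]][] <- 999 * random_connectome(14, seed = i)
  }
  tr2 <- mdmrnet:::subset_subjects(poisoned, sp$train)
  fs2 <- select_features(tr2, "key", B = 99, B_delta = 50, fallback_s = 2, seed = 5)
  expect_identical(fs1$edges, fs2$edges)
})

test_that("rank AUC matches the brute-force pairwise oracle and pROC", {
  set.seed(11)
  for (rep_ in 1:20) {
    scores <- sample(round(runif(30), 2))  # with ties
    truth <- runif(30) > 0.5
    if (!any(truth) || all(truth)) next
    expect_equal(mdmrnet:::rank_auc(scores, truth),
                 auc_oracle(scores, truth), tolerance = 1e-12)
  }
  skip_if_not_installed("pROC")
  scores <- runif(40); truth <- rep(c(TRUE, FALSE), 20)
  expect_equal(mdmrnet:::rank_auc(scores, truth),
               as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("rank AUC equals the trapezoidal integral of the empirical ROC", {
  set.seed(12)
  scores <- c(runif(15), runif(15) + 0.3)
  truth <- rep(c(FALSE, TRUE), each = 15)
  roc <- mdmrnet:::roc_points(scores, truth)
  trap <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  expect_equal(mdmrnet:::rank_auc(scores, truth), trap, tolerance = 1e-12)
})

test_that("a separable toy problem is fit perfectly with one component", {
  set.seed(5)
  X <- cbind(f1 = c(rnorm(20, -3), rnorm(20, 3)), f2 = rnorm(40))
  y <- factor(rep(c("CN", "AD"), each = 20), levels = c("CN", "AD"))
  mod <- train_plsda(X, y, positive = "AD", folds = 5, component_grid = 1:3,
                     seed = 1)
  ev <- evaluate_classifier(mod, X, y)
  expect_equal(ev$auc, 1)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)
  # invariance to feature order
  mod2 <- train_plsda(X[, 2:1], y, positive = "AD", folds = 5,
                      component_grid = 1:3, seed = 1)
  ev2 <- evaluate_classifier(mod2, X[, 2:1], y)
  expect_equal(ev$scores, ev2$scores, tolerance = 1e-10)
})

test_that("label-permuted training data gives chance-level CV AUC", {
  set.seed(6)
  X <- matrix(rnorm(40 * 25), 40); colnames(X) <- paste0("f", 1:25)
  aucs <- vapply(1:8, function(r) {
    y <- factor(sample(rep(c("CN", "AD"), each = 20)), levels = c("CN", "AD"))
    mod <- train_plsda(X, y, positive = "AD", folds = 5,
                       component_grid = 1:3, seed = r)
    max(mod$cv_auc)
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.15)
})

test_that("degenerate test sets are flagged and tied scores give AUC 0.5", {
  set.seed(7)
  X <- matrix(rnorm(30 * 4), 30); colnames(X) <- paste0("f", 1:4)
  y <- factor(rep(c("CN", "AD"), each = 15), levels = c("CN", "AD"))
  mod <- train_plsda(X, y, positive = "AD", folds = 3, component_grid = 1, seed = 2)
  ev <- evaluate_classifier(mod, X[y == "AD", , drop = FALSE], y[y == "AD"])
  expect_true(is.na(ev$auc))
  expect_identical(ev$flag, "single_class_test_set")
  expect_equal(mdmrnet:::rank_auc(rep(1, 10), rep(c(TRUE, FALSE), 5)), 0.5)
})

test_that("model comparison follows the paired-t limits and oracle", {
  m <- data.frame(sensitivity = c(0.8, 0.7, 0.9), specificity = c(0.6, 0.65, 0.7),
                  auc = c(0.75, 0.8, 0.85))
  same <- compare_models(m, m)
  expect_true(all(same$p == 1))
  shifted <- m; shifted[] <- m[] - 0.1
  const <- compare_models(m, shifted)
  expect_true(all(const$p == 0))
  m2 <- m; m2$auc <- c(0.70, 0.84, 0.80)
  got <- compare_models(m, m2)$p[3]
  expect_equal(got, t.test(m$auc - m2$auc)$p.value, tolerance = 1e-10)
  expect_error(compare_models(m[1, ], m2[1, ]))
})

test_that("the full protocol emits one row per comparison x mode x repeat", {
  cc <- small_cohort(seed = 21, effect = 3, n_nodes = 14,
                     groups = c(CN = 10, cMCI = 10, AD = 10), seeds = 4)
  rep_ <- run_classification(
    cc, comparisons = list(CN_vs_cMCI = c("CN", "cMCI"), CN_vs_AD = c("CN", "AD")),
    repeats = 2, folds = 3, B = 99, B_delta = 50, seed_p = 0.011,
    fallback_s = 2, component_grid = 1:3, test_fraction = 0.25, seed = 3
  )
  expect_identical(nrow(rep_$metrics), 2L * 2L * 2L)
  expect_true(all(rep_$metrics$auc >= 0 & rep_$metrics$auc <= 1, na.rm = TRUE))
  expect_true(all(c("key", "full") %in% rep_$metrics$mode))
  expect_identical(nrow(rep_$comparison), 6L)  # 2 comparisons x 3 metrics
})
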