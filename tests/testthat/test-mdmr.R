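# MDMR core: correlation distances, sum-of-squares decomposition,
# Gower trace identities, covariate adjustment, permutation inference,
# FDR.

test_that("correlation distance hits its closed-form anchor points", {
  v <- c(1, 2, 3, 5)
  expect_equal(correlation_distance(v, 2 * v + 1), 0)
  expect_equal(correlation_distance(v, -v), 2)
  # r = 0.5 by construction -> d = 1
  u <- c(1, -1, 0); w <- c(1, 0, -1)
  expect_equal(stats::cor(u, w), 0.5)
  expect_equal(correlation_distance(u, w), 1)
  # zero-variance vector: r defined as 0, d = sqrt(2), flagged
  d <- correlation_distance(c(1, 1, 1), c(1, 2, 3))
  expect_equal(as.numeric(d), sqrt(2))
  expect_true(isTRUE(attr(d, "degenerate")))
  expect_error(correlation_distance(1:3, 1:4), "length")
})

test_that("region distance matrix matches a brute-force pairwise loop", {
  cc <- small_cohort(seed = 2, n_nodes = 12, groups = c(CN = 4, AD = 4),
                     density = 0.5)
  D <- region_distance_matrix(cc, 5)
  n <- nrow(D)
  for (u in 1:n) for (v in 1:n) {
    du <- cc$connectomes[[u]][5, -5]
    dv <- cc$connectomes[[v]][5, -5]
    expected <- if (u == v) 0 else as.numeric(correlation_distance(du, dv))
    expect_equal(D[u, v], expected, tolerance = 1e-12)
  }
  expect_true(all(D >= 0 & D <= 2))
  # identical connectomes give an all-zero distance matrix
  same <- cc
  same$connectomes <- rep(cc$connectomes[1], 8)
  names(same$connectomes) <- names(cc$connectomes)
  expect_true(all(region_distance_matrix(same, 3) == 0))
})

test_that("pseudo-F decomposition reproduces the hand-worked example", {
  D <- matrix(2, 4, 4); diag(D) <- 0
  D[1, 2] <- D[2, 1] <- 1; D[3, 4] <- D[4, 3] <- 1
  f <- pseudo_f_groups(D, c("a", "a", "b", "b"))
  expect_equal(f$SST, 4.5)
  expect_equal(f$SSW, 1)
  expect_equal(f$SSA, 3.5)
  expect_equal(f$pseudo_F, 10.5)
  # equal distances: F = 1.5 regardless of the common value
  for (c_ in c(0.3, 1.7)) {
    Dc <- matrix(c_, 4, 4); diag(Dc) <- 0
    expect_equal(pseudo_f_groups(Dc, c("a", "a", "b", "b"))$pseudo_F, 1.5)
  }
  # SST ignores the labels
  D8 <- random_distance_matrix(8, seed = 5)
  l1 <- rep(c("a", "b"), each = 4)
  expect_equal(pseudo_f_groups(D8, l1)$SST,
               pseudo_f_groups(D8, sample(l1))$SST)
})

test_that("zero within-group distances give an infinite flagged statistic", {
  D <- matrix(2, 4, 4); diag(D) <- 0
  D[1, 2] <- D[2, 1] <- 0; D[3, 4] <- D[4, 3] <- 0
  f <- pseudo_f_groups(D, c("a", "a", "b", "b"))
  expect_identical(f$pseudo_F, Inf)
  expect_true(isTRUE(attr(f, "zero_within")))
})

test_that("Gower centering satisfies the distance-ANOVA trace identities", {
  expect_true(all(gower_center(matrix(0, 5, 5)) == 0))
  for (s in 1:100) {
    n <- sample(6:12, 1)
    D <- random_distance_matrix(n, seed = s)
    G <- gower_center(D)
    expect_lt(max(abs(rowSums(G))), 1e-10)
    k <- sample(2:3, 1)
    labels <- factor(rep_len(letters[1:k], n))
    ss <- pseudo_f_groups(D, labels)
    adj <- pseudo_f_adjusted(D, labels)
    expect_equal(adj$SSA, ss$SSA, tolerance = 1e-8)
    expect_equal(adj$SSW, ss$SSW, tolerance = 1e-8)
    expect_equal(sum(diag(G)), ss$SST, tolerance = 1e-8)
  }
})

test_that("the trace statistic agrees with an independent PERMANOVA implementation", {
  skip_if_not_installed("vegan")
  D <- random_distance_matrix(12, seed = 77)
  labels <- factor(rep(c("a", "b", "c"), each = 4))
  fit <- vegan::adonis2(stats::as.dist(D) ~ g,
                        data = data.frame(g = labels), permutations = 2)
  ss <- pseudo_f_groups(D, labels)
  expect_equal(ss$SSA, fit$SumOfSqs[1], tolerance = 1e-8)
  expect_equal(ss$SSW, fit$SumOfSqs[2], tolerance = 1e-8)
})

test_that("covariate adjustment nests the unadjusted statistic", {
  D <- random_distance_matrix(10, seed = 9)
  labels <- rep(c("a", "b"), each = 5)
  plain <- pseudo_f_adjusted(D, labels)
  expect_equal(plain$pseudo_F, pseudo_f_groups(D, labels)$pseudo_F,
               tolerance = 1e-10)
  # constant covariate column is dropped and changes nothing
  cov1 <- data.frame(age = rep(70, 10))
  adj <- pseudo_f_adjusted(D, labels, cov1)
  expect_equal(adj$pseudo_F, plain$pseudo_F, tolerance = 1e-10)
  expect_identical(adj$dropped, "age")
  # collinear covariates are a named error
  cov2 <- data.frame(age = 1:10, age2 = 2 * (1:10))
  expect_error(pseudo_f_adjusted(D, labels, cov2), "age2")
})

test_that("covariate adjustment removes a planted age confound", {
  set.seed(42)
  n <- 40
  group <- rep(c("CN", "AD"), each = n / 2)
  age <- ifelse(group == "AD", 80, 70) + rnorm(n, 0, 2)
  # the connectivity *pattern* rotates with age and with nothing else;
  # the group difference exists only through the age confound
  v1 <- runif(20, 0.5, 1.5); v2 <- rnorm(20)
  X <- outer(rep(1, n), v1) * 10 + outer((age - 75) / 5, v2) +
    matrix(rnorm(n * 20, 0, 0.5), n)
  D <- mdmrnet:::dist_from_profiles(X)
  raw <- mdmr_permutation_test(D, group, NULL, B = 199, seed = 1)
  adj <- mdmr_permutation_test(D, group, data.frame(age = age), B = 199, seed = 1)
  expect_lt(raw$p, 0.05)
  expect_gt(adj$p, 0.05)
})

test_that("permutation p-values follow the add-one counting convention", {
  # strong separation: observed F beats every permutation
  cc <- small_cohort(seed = 5, effect = 4, n_nodes = 20,
                     groups = c(CN = 10, AD = 10), seeds = 4)
  D <- region_distance_matrix(cc, 4)
  pt <- mdmr_permutation_test(D, cc$cohort$group, NULL, B = 99, seed = 3)
  expect_equal(pt$p, 1 / 100)
  # all-equal distances: every permutation ties the observed value
  Deq <- matrix(1, 8, 8); diag(Deq) <- 0
  pt2 <- mdmr_permutation_test(Deq, rep(c("a", "b"), each = 4), NULL,
                               B = 99, seed = 3)
  expect_equal(pt2$p, 1)
})

test_that("printed, dof-scaled and trace forms give identical exhaustive p-values", {
  for (s in 1:5) {
    D <- random_distance_matrix(6, seed = 200 + s)
    labels <- factor(c("a", "a", "a", "b", "b", "b"))
    perms <- mdmrnet:::all_permutations(6)
    n <- 6; k <- 2
    f_printed <- vapply(perms, function(p)
      pseudo_f_groups(D[p, p], labels)$pseudo_F, numeric(1))
    f_classic <- vapply(perms, function(p) {
      ss <- pseudo_f_groups(D[p, p], labels)
      (ss$SSA / (k - 1)) / (ss$SSW / (n - k))
    }, numeric(1))
    p_printed <- mean(f_printed >= f_printed[1] - 1e-12)
    p_classic <- mean(f_classic >= f_classic[1] - 1e-12)
    p_trace <- mdmr_permutation_test(D, labels, exhaustive = TRUE)$p
    expect_equal(p_printed, p_classic)
    expect_equal(p_trace, p_printed)
  }
})

test_that("BH correction matches the step-up oracle and preserves order", {
  expect_equal(fdr_correct(0.037), 0.037)
  expect_equal(fdr_correct(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_correct(rep(1, 5)), rep(1, 5))
  set.seed(8)
  p <- runif(90)
  q <- fdr_correct(p)
  expect_equal(q, bh_oracle(p))
  expect_true(all(q[order(p)] == cummax(q[order(p)])))
  expect_true(all(q >= p))
  expect_error(fdr_correct(c(0, 0.5)))
})

test_that("run_mdmr is deterministic, per-comparison, and errors on missing groups", {
  cc <- small_cohort(seed = 31, effect = 3, n_nodes = 12,
                     groups = c(CN = 6, AD = 6), seeds = 2)
  m1 <- run_mdmr(cc, list(a = c("CN", "AD")), B = 99, seed = 5)
  m2 <- run_mdmr(cc, list(a = c("CN", "AD")), B = 99, seed = 5)
  expect_identical(m1, m2)
  expect_named(m1, "a")
  expect_identical(nrow(m1$a), 12L)
  expect_error(run_mdmr(cc, list(bad = c("CN", "cMCI")), B = 99, seed = 1),
               "absent")
})
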