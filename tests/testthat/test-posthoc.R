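# Post-hoc: delta connection effect sizes, top-k extraction, nodal
# strength and its group comparisons.

# Hand-built two-group cohort where exactly one edge (seed--partner)
# carries the whole group effect.
single_edge_cohort <- function(n_per = 8, n_nodes = 10, seed = 1,
                               edge = c(1, 5), shift = 3) {
  set.seed(seed)
  mats <- list()
  cohort <- data.frame(subject_id = sprintf("S%02d", 1:(2 * n_per)),
                       group = rep(c("CN", "AD"), each = n_per),
                       age = rnorm(2 * n_per, 74, 5),
                       sex = sample(c("F", "M"), 2 * n_per, TRUE),
                       apoe4 = rbinom(2 * n_per, 1, 0.2),
                       stringsAsFactors = FALSE)
  base <- random_connectome(n_nodes, seed = seed + 100)
  for (i in seq_len(2 * n_per)) {
    w <- base * exp(matrix(0, n_nodes, n_nodes))
    noise <- matrix(rnorm(n_nodes^2, 0, 0.05), n_nodes)
    noise <- (noise + t(noise)) / 2
    w <- pmax(base + noise, 0)
    w <- (w + t(w)) / 2; diag(w) <- 0
    if (cohort$group[i] == "AD") {
      w[edge[1], edge[2]] <- w[edge[1], edge[2]] + shift
      w[edge[2], edge[1]] <- w[edge[1], edge[2]]
    }
    dimnames(w) <- dimnames(base)
    mats[[cohort$subject_id[i]]] <- w
  }
  connectome_cohort(cohort, mats)
}

test_that("delta attains its maximum at the edge carrying the group effect", {
  cc <- single_edge_cohort()
  eff <- delta_effect_size(cc, 1, covariates = NULL, B_delta = 50, seed = 2)
  expect_identical(eff$partner[which.max(eff$delta)], 5L)
  expect_identical(eff$rank[eff$partner == 5], 1L)
})

test_that("delta is zero for constant columns and near zero under the null", {
  cc <- small_cohort(seed = 6, n_nodes = 12, groups = c(CN = 8, AD = 8),
                     density = 0.4)
  # make one partner's column constant (edge absent everywhere)
  for (id in names(cc$connectomes)) {
    cc$connectomes[[id]][2, 7] <- 0
    cc$connectomes[[id]][7, 2] <- 0
  }
  eff <- delta_effect_size(cc, 2, covariates = NULL, B_delta = 50, seed = 3)
  expect_equal(eff$delta[eff$partner == 7], 0)
  expect_identical(eff$flag[eff$partner == 7], "degenerate")
  # null cohort: mean delta across edges is small
  expect_lt(abs(mean(eff$delta)), 0.05)
})

test_that("top-k extraction ranks, deduplicates seeds, and flags ties", {
  eff <- data.frame(seed = 1L, seed_label = "A",
                    partner = 2:7, partner_label = letters[2:7],
                    delta = c(0.5, 0.4, 0.3, 0.2, 0.1, 0.05),
                    rank = 1:6, flag = "")
  top1 <- top_k_connections(eff, k = 1)
  expect_identical(top1$partner, 2L)
  # all equal: first k in node order with the tie flag set
  eff$delta <- 0.2
  topt <- top_k_connections(eff, k = 3)
  expect_identical(topt$partner, 2:4)
  expect_true(all(topt$tie))
  # fewer than k finite entries
  eff2 <- eff[1:2, ]; eff2$delta <- c(0.3, 0.1)
  short <- top_k_connections(eff2, k = 5)
  expect_identical(nrow(short), 2L)
  expect_true(all(short$flag == "fewer_than_k"))
})

test_that("nodal strength equals the L1 norm of the node row", {
  w <- random_connectome(12, seed = 9)
  for (i in c(1, 5, 12)) expect_equal(nodal_strength(w, i), sum(abs(w[i, ])))
  w0 <- w; w0[4, ] <- 0; w0[, 4] <- 0
  expect_equal(nodal_strength(w0, 4), 0)
  w3 <- matrix(0, 4, 4)
  w3[1, 2] <- w3[2, 1] <- 0.1; w3[1, 3] <- w3[3, 1] <- 0.2
  dimnames(w3) <- list(node_labels(4), node_labels(4))
  expect_equal(nodal_strength(w3, 1), 0.3)
  # thresholding never increases strength
  thr <- apply_density_threshold(w, 0.3)
  for (i in 1:12) expect_lte(nodal_strength(thr, i), nodal_strength(w, i))
})

test_that("strength GLM matches a hand partial-F computation", {
  set.seed(4)
  n <- 24
  cohort <- data.frame(subject_id = sprintf("S%02d", 1:n),
                       group = rep(c("CN", "cMCI", "AD"), each = 8),
                       age = rnorm(n, 74, 5),
                       sex = sample(c("F", "M"), n, TRUE),
                       apoe4 = rbinom(n, 1, 0.2))
  strengths <- data.frame(subject_id = cohort$subject_id, node = 1L,
                          node_label = "R001",
                          strength = rnorm(n, 10) - 2 * (cohort$group == "AD"))
  res <- strength_group_glm(strengths, cohort, 1)
  # independent partial-F from residual sums of squares
  df <- merge(strengths, cohort, by = "subject_id")
  m0 <- lm(strength ~ age + sex + apoe4, df)
  m1 <- lm(strength ~ group + age + sex + apoe4, df)
  rss0 <- sum(resid(m0)^2); rss1 <- sum(resid(m1)^2)
  df1 <- 2; df2 <- n - length(coef(m1))
  Fo <- ((rss0 - rss1) / df1) / (rss1 / df2)
  expect_equal(res$F, Fo, tolerance = 1e-8)
  expect_equal(res$p, pf(Fo, df1, df2, lower.tail = FALSE), tolerance = 1e-8)
  # identical strengths: no group effect, p = 1
  strengths$strength <- 7
  expect_equal(strength_group_glm(strengths, cohort, 1)$p, 1)
})

test_that("a planted amplitude reduction is detected by the strength GLM", {
  ps <- vapply(13:17, function(seed) {
    cc <- small_cohort(seed = seed, effect = 4, n_nodes = 20,
                       groups = c(CN = 30, AD = 30), seeds = 6)
    st <- nodal_strength_table(cc, 6)
    strength_group_glm(st, cc$cohort, 6)$p
  }, numeric(1))
  expect_lt(median(ps), 0.05)
})

test_that("pairwise strength permutation is symmetric and saturates on separation", {
  set.seed(10)
  n <- 20
  cohort <- data.frame(subject_id = sprintf("S%02d", 1:n),
                       group = rep(c("CN", "AD"), each = 10),
                       age = rnorm(n, 74, 5),
                       sex = sample(c("F", "M"), n, TRUE),
                       apoe4 = rbinom(n, 1, 0.2))
  # disjoint strength supports
  strengths <- data.frame(subject_id = cohort$subject_id, node = 1L,
                          node_label = "R001",
                          strength = c(rnorm(10, 100, 1), rnorm(10, 5, 1)))
  p1 <- pairwise_strength_permutation(strengths, cohort, 1, c("CN", "AD"),
                                      covariates = NULL, B = 99, seed = 1)
  expect_equal(p1$p, 1 / 100)
  p2 <- pairwise_strength_permutation(strengths, cohort, 1, c("AD", "CN"),
                                      covariates = NULL, B = 99, seed = 1)
  expect_equal(p1$p, p2$p)
  expect_error(pairwise_strength_permutation(strengths, cohort, 1,
                                             c("CN", "cMCI"), B = 99),
               "absent")
})
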