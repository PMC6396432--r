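# Post-hoc attribution of a significant regional MDMR association to
# individual connections (randomization-based delta effect size, top-k
# extraction) and group comparison of overall nodal connectivity
# strength.

#' Randomization-based connection effect size (delta)
#'
#' Attributes a seed region's multivariate group association to its
#' individual connections.  For each partner edge `j` of the seed's
#' connectivity vectors,
#' \deqn{\delta_j = R^2_{pseudo}(\mathrm{orig}) -
#'   \overline{R^2_{pseudo}(\mathrm{col}\ j\ \mathrm{permuted})},}
#' where the pseudo-\eqn{R^2} is \eqn{\mathrm{tr}(H_\Delta G)/
#' \mathrm{tr}(G)} (SSA/SST without covariates) recomputed from the
#' seed's correlation-distance matrix after independently permuting
#' column `j` across subjects, averaged over `B_delta` randomizations.
#' A large \eqn{\delta_j} means destroying edge `j`'s subject ordering
#' removes much of the association, i.e. the edge drives it.
#'
#' @param cc A `"connectome_cohort"` (already subset to the compared
#'   groups).
#' @param seed_region Node index or label (caller is responsible for
#'   picking MDMR-significant seeds).
#' @param covariates Character vector of cohort covariate columns, or
#'   `NULL`.
#' @param B_delta Randomizations per column (>= 50; default 100).
#' @param seed Integer seed.
#' @return Data frame (class `"effect_size_table"`) with one row per
#'   partner: `seed`, `seed_label`, `partner`, `partner_label`,
#'   `delta`, `rank` (1 = largest delta), `flag` (`"degenerate"` for
#'   all-constant columns, for which delta is 0 by construction).
#' @export
delta_effect_size <- function(cc, seed_region,
                              covariates = c("age", "sex", "apoe4"),
                              B_delta = 100, seed = 1L) {
  stopifnot(inherits(cc, "connectome_cohort"))
  if (B_delta < 50) stop("B_delta must be >= 50")
  mats <- cc$connectomes
  i <- resolve_node(mats[[1]], seed_region)
  n_nodes <- nrow(mats[[1]])
  X <- t(vapply(mats, function(m) m[i, -i], numeric(n_nodes - 1L)))
  rownames(X) <- names(mats)
  labels <- cc$cohort$group
  cov_df <- if (length(covariates)) cc$cohort[, covariates, drop = FALSE] else NULL
  n <- nrow(X)

  Z <- covariate_design(cov_df, n)
  Xg <- stats::model.matrix(~ labels)[, -1, drop = FALSE]
  Hd <- hat_matrix(cbind(Z, Xg)) - hat_matrix(Z)
  r2 <- function(Xmat) {
    G <- gower_center(dist_from_profiles(Xmat))
    sst <- sum(diag(G))
    if (sst == 0) return(0)
    sum(Hd * G) / sst
  }
  r2_orig <- r2(X)

  partners <- setdiff(seq_len(n_nodes), i)
  delta <- numeric(length(partners))
  flag <- character(length(partners))
  with_seed_(seed, {
    for (j in seq_along(partners)) {
      col <- X[, j]
      if (stats::var(col) == 0) {
        delta[j] <- 0
        flag[j] <- "degenerate"
        next
      }
      r2_perm <- numeric(B_delta)
      Xp <- X
      for (b in seq_len(B_delta)) {
        Xp[, j] <- col[sample.int(n)]
        r2_perm[b] <- r2(Xp)
      }
      delta[j] <- r2_orig - mean(r2_perm)
    }
  })
  vocab <- rownames(mats[[1]])
  out <- data.frame(
    seed = i, seed_label = vocab[i],
    partner = partners, partner_label = vocab[partners],
    delta = delta,
    rank = rank(-delta, ties.method = "first"),
    flag = flag, stringsAsFactors = FALSE
  )
  class(out) <- c("effect_size_table", "data.frame")
  out
}

#' Top-k connections by effect size
#'
#' The `k` partner connections with the largest delta per seed region
#' (conventionally the top five per seed).  Ties are broken by node
#' order and flagged; if fewer than `k` finite entries exist, all are
#' returned with a flag.
#'
#' @param effects An `"effect_size_table"` (rows for one or more
#'   seeds).
#' @param k Connections to keep per seed (default 5).
#' @return Data frame of the selected rows, ordered by seed then rank,
#'   with a logical `tie` column.
#' @export
top_k_connections <- function(effects, k = 5) {
  stopifnot(is.data.frame(effects), k >= 1)
  out <- do.call(rbind, lapply(split(effects, effects$seed), function(df) {
    df <- df[is.finite(df$delta), , drop = FALSE]
    ord <- order(-df$delta, df$partner)
    kk <- min(k, nrow(df))
    sel <- df[ord[seq_len(kk)], , drop = FALSE]
    sel$rank <- seq_len(kk)
    # a tie at the boundary: the first excluded delta equals the last kept
    sel$tie <- FALSE
    if (nrow(df) > kk && df$delta[ord[kk + 1]] == sel$delta[kk]) sel$tie <- TRUE
    if (kk < k) sel$flag <- ifelse(sel$flag == "", "fewer_than_k", sel$flag)
    sel
  }))
  rownames(out) <- NULL
  out
}

#' Nodal overall connectivity strength
#'
#' The sum of absolute edge weights incident to a node — the amplitude
#' (as opposed to pattern) summary of a region's connectivity.
#'
#' @param w Connectome matrix.
#' @param node Node index or label.
#' @return Nonnegative scalar; 0 for an isolated node.
#' @export
nodal_strength <- function(w, node) {
  w <- validate_connectome(w)
  i <- resolve_node(w, node)
  sum(abs(w[i, ]))
}

#' Nodal strength table for a cohort
#'
#' @param cc A `"connectome_cohort"`.
#' @param nodes Node indices or labels (default all).
#' @return Data frame `subject_id`, `node`, `node_label`, `strength`.
#' @export
nodal_strength_table <- function(cc, nodes = NULL) {
  stopifnot(inherits(cc, "connectome_cohort"))
  vocab <- rownames(cc$connectomes[[1]])
  if (is.null(nodes)) nodes <- seq_along(vocab)
  idx <- vapply(nodes, function(nd) resolve_node(cc$connectomes[[1]], nd), 0L)
  out <- do.call(rbind, lapply(names(cc$connectomes), function(id) {
    w <- cc$connectomes[[id]]
    data.frame(subject_id = id, node = idx, node_label = vocab[idx],
               strength = vapply(idx, function(i) sum(abs(w[i, ])), 0),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Group effect on nodal strength (general linear model)
#'
#' OLS fit of one node's strength on group indicators plus covariates;
#' the group effect is tested by the partial F comparing the covariate
#' model against the full model.
#'
#' @param strengths Output of [nodal_strength_table()] (or compatible
#'   data frame) for the tested node.
#' @param cohort Cohort data frame aligned by `subject_id`.
#' @param node Node index to test.
#' @param covariates Character vector of covariate columns, or `NULL`.
#' @return List with `p` (partial-F p-value), `F`, `df`, and the
#'   fitted `lm` object.
#' @export
strength_group_glm <- function(strengths, cohort, node,
                               covariates = c("age", "sex", "apoe4")) {
  df <- strengths[strengths$node == node, , drop = FALSE]
  df <- merge(df, cohort, by = "subject_id", sort = TRUE)
  df$group <- droplevels(as.factor(df$group))
  rhs0 <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  f0 <- stats::as.formula(paste("strength ~", rhs0))
  f1 <- stats::as.formula(paste("strength ~ group +", rhs0))
  m0 <- stats::lm(f0, data = df)
  m1 <- stats::lm(f1, data = df)
  if (any(is.na(stats::coef(m1)))) {
    bad <- names(stats::coef(m1))[is.na(stats::coef(m1))]
    stop("rank-deficient design; aliased term(s): ", paste(bad, collapse = ", "))
  }
  an <- stats::anova(m0, m1)
  Fv <- an$F[2]
  p <- an$`Pr(>F)`[2]
  # no strength variation at all (e.g. identical strengths): zero group SS
  scale2 <- max(1, mean(df$strength)^2)
  if (is.na(Fv) || sum(stats::resid(m0)^2) < 1e-16 * scale2) {
    Fv <- 0
    p <- 1
  }
  list(p = p, F = Fv, df = c(an$Df[2], an$Res.Df[2]), fit = m1)
}

#' Pairwise permutation test on covariate-adjusted nodal strength
#'
#' Two-sided permutation test of the mean-strength difference between
#' two named groups at one node.  Strengths are first residualized on
#' the covariates (both groups pooled), then the absolute difference of
#' group mean residuals is compared against its permutation
#' distribution under group-label shuffling; add-one convention.
#'
#' @param strengths Nodal strength table rows.
#' @param cohort Cohort data frame.
#' @param node Node index.
#' @param group_pair Character vector of the two group labels.
#' @param covariates Covariate columns, or `NULL`.
#' @param B Number of permutations.
#' @param seed Integer seed.
#' @return List with `p`, `observed` (absolute adjusted mean
#'   difference), `B`.
#' @export
pairwise_strength_permutation <- function(strengths, cohort, node, group_pair,
                                          covariates = c("age", "sex", "apoe4"),
                                          B = 5000, seed = 1L) {
  stopifnot(length(group_pair) == 2L)
  if (!all(group_pair %in% as.character(cohort$group))) {
    stop("group(s) absent from cohort: ",
         paste(setdiff(group_pair, as.character(cohort$group)), collapse = ", "))
  }
  df <- strengths[strengths$node == node, , drop = FALSE]
  df <- merge(df, cohort, by = "subject_id", sort = TRUE)
  df <- df[df$group %in% group_pair, , drop = FALSE]
  if (length(covariates)) {
    rhs <- paste(covariates, collapse = " + ")
    res <- stats::resid(stats::lm(stats::as.formula(paste("strength ~", rhs)),
                                  data = df))
  } else {
    res <- df$strength - mean(df$strength)
  }
  is_a <- df$group == group_pair[1]
  stat <- function(ind) abs(mean(res[ind]) - mean(res[!ind]))
  obs <- stat(is_a)
  n <- length(res)
  perm <- with_seed_(seed, {
    vapply(seq_len(B), function(b) stat(sample(is_a)), numeric(1))
  })
  list(p = (1 + sum(perm >= obs - 1e-12)) / (B + 1), observed = obs, B = B)
}
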