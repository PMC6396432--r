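# PLS-DA classification of diagnostic group from structural
# connectivity: repeated stratified train/test splits, training-side
# feature selection (MDMR seeds + delta top-k edges vs. the full
# upper-triangle), cross-validated component tuning, and test-set
# sensitivity / specificity / ROC / AUC, with a paired comparison of
# the key-connection and whole-brain feature sets.

#' Stratified train/test split
#'
#' Random split with per-class allocation by largest remainder, so the
#' overall test size is `round(test_fraction * n)` (e.g. 32 of 161 at
#' the default 0.2) and class proportions are preserved as closely as
#' possible.
#'
#' @param labels Class label per subject.
#' @param test_fraction Fraction held out (default 0.2).
#' @param seed Integer seed (one per repeat).
#' @return List with integer index vectors `train` and `test`.
#' @export
split_cohort <- function(labels, test_fraction = 0.2, seed = 1L) {
  labels <- as.factor(labels)
  n <- length(labels)
  if (any(table(labels) < 5)) stop("every class needs >= 5 members for stratified splitting")
  target <- round(test_fraction * n)
  tab <- table(labels)
  ideal <- test_fraction * as.numeric(tab)
  base <- floor(ideal)
  extra <- target - sum(base)
  if (extra > 0) {
    ord <- order(ideal - base, decreasing = TRUE)
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
  } else if (extra < 0) {
    ord <- order(ideal - base)
    base[ord[seq_len(-extra)]] <- base[ord[seq_len(-extra)]] - 1
  }
  test <- with_seed_(seed, {
    unlist(lapply(seq_along(tab), function(ci) {
      idx <- which(labels == names(tab)[ci])
      sample(idx, base[ci])
    }), use.names = FALSE)
  })
  test <- sort(test)
  list(train = setdiff(seq_len(n), test), test = test)
}

#' Select connectivity features on the training subjects
#'
#' `mode = "full"`: every upper-triangle node pair (4005 for 90
#' nodes).  `mode = "key"`: rerun the MDMR scan on the *training*
#' subjects only, take seed regions below the significance threshold
#' (falling back to the `fallback_s` smallest-p regions when none
#' qualifies, flagged), compute delta effect sizes per seed, and pool
#' the deduplicated union of each seed's top-`k` edges.  Test subjects
#' are never touched, so downstream evaluation is leak-free.
#'
#' @param cc_train Training-subject `"connectome_cohort"` (binary
#'   comparison).
#' @param mode `"key"` or `"full"`.
#' @param covariates Covariate columns for the MDMR/delta reruns.
#' @param B Permutations for the training MDMR scan.
#' @param B_delta Randomizations for delta.
#' @param seed_p Seed-region significance threshold on the permutation
#'   p (default 0.001, as used for post-hoc seed selection).
#' @param k Top connections per seed (default 5).
#' @param fallback_s Number of smallest-p regions used when no region
#'   passes `seed_p` (default 9, the seed count of the motivating
#'   analysis).
#' @param seed Integer seed.
#' @return List (class `"feature_set"`): `mode`, `edges` (two-column
#'   matrix, i < j), `names`, `provenance` (for key mode the
#'   seed/partner/delta records), `fallback` flag.
#' @export
select_features <- function(cc_train, mode = c("key", "full"),
                            covariates = c("age", "sex", "apoe4"),
                            B = 199, B_delta = 50, seed_p = 0.001,
                            k = 5, fallback_s = 9, seed = 1L) {
  mode <- match.arg(mode)
  n_nodes <- nrow(cc_train$connectomes[[1]])
  vocab <- rownames(cc_train$connectomes[[1]])
  if (mode == "full") {
    pairs <- upper_triangle_pairs(n_nodes)
    fs <- list(mode = "full", edges = pairs,
               names = paste0(vocab[pairs[, 1]], "--", vocab[pairs[, 2]]),
               provenance = NULL, fallback = FALSE)
    class(fs) <- "feature_set"
    return(fs)
  }
  seeds <- derive_seeds(seed, 2L)
  comp <- list(train = levels(cc_train$cohort$group))
  scan <- run_mdmr(cc_train, comp, covariates = covariates, B = B,
                   seed = seeds[1])$train
  sig <- scan$region[scan$p_perm < seed_p]
  fallback <- FALSE
  if (!length(sig)) {
    fallback <- TRUE
    s <- min(fallback_s, nrow(scan))
    sig <- scan$region[order(scan$p_perm, scan$region)][seq_len(s)]
  }
  eff <- do.call(rbind, lapply(seq_along(sig), function(ii) {
    delta_effect_size(cc_train, sig[ii], covariates = covariates,
                      B_delta = B_delta, seed = seeds[2] + ii)
  }))
  top <- top_k_connections(eff, k = k)
  edges <- cbind(pmin(top$seed, top$partner), pmax(top$seed, top$partner))
  keep <- !duplicated(edges)
  edges <- edges[keep, , drop = FALSE]
  colnames(edges) <- c("i", "j")
  fs <- list(mode = "key", edges = edges,
             names = paste0(vocab[edges[, 1]], "--", vocab[edges[, 2]]),
             provenance = top, fallback = fallback)
  class(fs) <- "feature_set"
  fs
}

# Feature matrix (subjects x edges) for a feature set.
feature_matrix <- function(cc, feature_set) {
  edges <- feature_set$edges
  X <- t(vapply(cc$connectomes,
                function(w) w[cbind(edges[, 1], edges[, 2])],
                numeric(nrow(edges))))
  colnames(X) <- feature_set$names
  rownames(X) <- names(cc$connectomes)
  X
}

#' Train a tuned PLS-DA classifier
#'
#' Partial least squares discriminant analysis on the training
#' features, with the number of latent components chosen by stratified
#' k-fold cross-validation maximizing pooled CV AUC over a grid
#' (smallest component count wins ties).  The grid is truncated to the
#' feasible rank and the truncation flagged.
#'
#' @param X Training feature matrix (subjects x features).
#' @param y Class labels (2 levels; the patient class is taken as the
#'   positive class, see [evaluate_classifier()]).
#' @param positive Positive-class label (default: second level of `y`).
#' @param folds Cross-validation folds (default 5).
#' @param component_grid Candidate component counts (default 1:10).
#' @param seed Integer seed for fold assignment.
#' @return List (class `"plsda_model"`): the fitted mixOmics model,
#'   `ncomp` chosen, `cv_auc` per grid point, `positive`,
#'   `truncated` flag.
#' @export
train_plsda <- function(X, y, positive = NULL, folds = 5,
                        component_grid = 1:10, seed = 1L) {
  y <- droplevels(as.factor(y))
  stopifnot(nlevels(y) == 2L)
  if (is.null(positive)) positive <- levels(y)[2]
  if (any(table(y) < folds)) stop("each class needs >= folds subjects")
  keep <- apply(X, 2, stats::var) > 0
  if (!any(keep)) stop("all features are constant")
  X <- X[, keep, drop = FALSE]
  max_comp <- max_components(X)
  grid <- component_grid[component_grid <= max_comp]
  truncated <- length(grid) < length(component_grid)
  if (!length(grid)) grid <- 1L
  fold_id <- with_seed_(seed, {
    id <- integer(length(y))
    for (lv in levels(y)) {
      idx <- sample(which(y == lv))
      id[idx] <- rep_len(seq_len(folds), length(idx))
    }
    id
  })
  scores_cv <- matrix(NA_real_, length(y), length(grid))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    fit <- plsda_fit(X[tr, , drop = FALSE], y[tr], max(grid))
    pr <- plsda_scores(fit, X[!tr, , drop = FALSE], positive, grid)
    scores_cv[!tr, ] <- pr
  }
  cv_auc <- apply(scores_cv, 2, function(s) rank_auc(s, y == positive))
  best <- grid[which.max(cv_auc)]
  final <- plsda_fit(X, y, best)
  out <- list(fit = final, ncomp = best, cv_auc = stats::setNames(cv_auc, grid),
              positive = positive, levels = levels(y),
              features = colnames(X), truncated = truncated)
  class(out) <- "plsda_model"
  out
}

# Feasible PLS component count: bounded by the rank of the centered
# feature matrix (deflation exhausts beyond it) and the sample size.
max_components <- function(X) {
  r <- qr(sweep(X, 2, colMeans(X)))$rank
  max(1L, min(r - 1L, ncol(X), nrow(X) - 2L))
}

# Fit a mixOmics PLS-DA with ncomp components.  Warnings from the
# explained-variance bookkeeping (cor against within-fold-constant
# columns) are benign and silenced.
plsda_fit <- function(X, y, ncomp) {
  ncomp <- min(ncomp, max_components(X))
  suppressWarnings(mixOmics::plsda(X, y, ncomp = ncomp, scale = FALSE))
}

# Predicted positive-class indicator scores for each requested
# component count (columns).
plsda_scores <- function(fit, X_new, positive, ncomps) {
  pr <- stats::predict(fit, X_new)$predict  # subjects x classes x ncomp
  ncomps <- pmin(ncomps, dim(pr)[3])
  sapply(ncomps, function(nc) pr[, positive, nc])
}

# Mann-Whitney rank AUC of scores for a binary truth vector
# (midranks, so tied scores count 1/2).
rank_auc <- function(scores, is_pos) {
  n1 <- sum(is_pos)
  n0 <- sum(!is_pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a PLS-DA model on held-out subjects
#'
#' Test-set sensitivity (true-positive rate on the patient class),
#' specificity, the empirical ROC curve, and its AUC computed by the
#' rank (Mann-Whitney) formula on the continuous positive-class
#' scores.  Class calls use the 0.5 threshold on the predicted class
#' indicator.
#'
#' @param model A `"plsda_model"`.
#' @param X_test,y_test Held-out features and labels (must be disjoint
#'   from training).
#' @param threshold Decision threshold on the positive-class score.
#' @return List with `sensitivity`, `specificity`, `auc`, `roc` (data
#'   frame of fpr/tpr points), `scores`.  With a single-class test set
#'   AUC is `NA` and flagged.
#' @export
evaluate_classifier <- function(model, X_test, y_test, threshold = 0.5) {
  y_test <- factor(as.character(y_test), levels = model$levels)
  X_test <- X_test[, model$features, drop = FALSE]
  scores <- as.matrix(plsda_scores(model$fit, X_test, model$positive,
                                   model$ncomp))[, 1]
  is_pos <- y_test == model$positive
  pred_pos <- scores >= threshold
  sens <- if (any(is_pos)) mean(pred_pos[is_pos]) else NA_real_
  spec <- if (any(!is_pos)) mean(!pred_pos[!is_pos]) else NA_real_
  auc <- rank_auc(scores, is_pos)
  out <- list(sensitivity = sens, specificity = spec, auc = auc,
              roc = roc_points(scores, is_pos), scores = scores)
  if (!any(is_pos) || !any(!is_pos)) out$flag <- "single_class_test_set"
  out
}

# Empirical ROC points over all score thresholds (decreasing), from
# (0,0) to (1,1).
roc_points <- function(scores, is_pos) {
  ths <- c(Inf, sort(unique(scores), decreasing = TRUE))
  data.frame(
    threshold = ths,
    fpr = vapply(ths, function(t) mean(scores[!is_pos] >= t), 0),
    tpr = vapply(ths, function(t) mean(scores[is_pos] >= t), 0)
  )
}

#' Paired comparison of key-feature and full-feature performance
#'
#' Paired two-sided t-tests on the per-resample differences of each
#' metric between the two feature modes.  Degenerate cases follow the
#' limits of the t statistic: all differences zero gives p = 1; a
#' nonzero constant difference gives p = 0.
#'
#' @param key,full Data frames of per-resample metrics (same resample
#'   order) with columns among `sensitivity`, `specificity`, `auc`.
#' @return Data frame with `metric`, `mean_diff` (key - full), `p`.
#' @export
compare_models <- function(key, full) {
  stopifnot(nrow(key) == nrow(full), nrow(key) >= 2)
  metrics <- intersect(c("sensitivity", "specificity", "auc"), names(key))
  do.call(rbind, lapply(metrics, function(m) {
    d <- key[[m]] - full[[m]]
    d <- d[is.finite(d)]
    if (length(d) < 2) {
      p <- NA_real_
    } else if (stats::sd(d) <= 1e-10 * max(1, abs(mean(d)))) {
      # degenerate paired t: constant differences
      p <- if (abs(mean(d)) <= 1e-12) 1 else 0
    } else {
      p <- stats::t.test(d)$p.value
    }
    data.frame(metric = m, mean_diff = mean(d), p = p,
               stringsAsFactors = FALSE)
  }))
}

#' Run the full classification protocol
#'
#' For each binary comparison (default CN vs. cMCI and CN vs. AD) and
#' each feature mode: repeated stratified train/test splits,
#' training-side feature selection, k-fold-tuned PLS-DA, and test-set
#' evaluation; then a paired key-vs-full comparison per metric.
#'
#' @param cc A `"connectome_cohort"`.
#' @param comparisons Named list of 2-group label vectors.
#' @param modes Feature modes to run (default both).
#' @param repeats Train/test repetitions (default 5).
#' @param folds CV folds for component tuning (default 5).
#' @param test_fraction Held-out fraction (default 0.2).
#' @param covariates,B,B_delta,seed_p,k,fallback_s Passed to
#'   [select_features()].
#' @param component_grid Candidate PLS component counts.
#' @param seed Master seed.
#' @return List (class `"classification_report"`): `metrics` (data
#'   frame: comparison, mode, repeat, ncomp, sensitivity, specificity,
#'   auc, n_features), `summary` (means over repeats), `comparison`
#'   (key-vs-full paired tests per comparison).
#' @export
run_classification <- function(cc,
                               comparisons = list(CN_vs_cMCI = c("CN", "cMCI"),
                                                  CN_vs_AD = c("CN", "AD")),
                               modes = c("key", "full"),
                               repeats = 5, folds = 5, test_fraction = 0.2,
                               covariates = c("age", "sex", "apoe4"),
                               B = 199, B_delta = 50, seed_p = 0.001,
                               k = 5, fallback_s = 9,
                               component_grid = 1:10, seed = 1L) {
  stopifnot(inherits(cc, "connectome_cohort"))
  rows <- list()
  seeds <- derive_seeds(seed, length(comparisons) * repeats * 3L)
  si <- 0L
  for (cmp in names(comparisons)) {
    pair <- comparisons[[cmp]]
    sub <- subset_cohort(cc, pair)
    positive <- pair[2]  # patient class
    for (r in seq_len(repeats)) {
      si <- si + 3L
      sp <- split_cohort(sub$cohort$group, test_fraction, seed = seeds[si - 2])
      cc_tr <- subset_subjects(sub, sp$train)
      cc_te <- subset_subjects(sub, sp$test)
      for (mode in modes) {
        fs <- select_features(cc_tr, mode, covariates = covariates, B = B,
                              B_delta = B_delta, seed_p = seed_p, k = k,
                              fallback_s = fallback_s, seed = seeds[si - 1])
        Xtr <- feature_matrix(cc_tr, fs)
        Xte <- feature_matrix(cc_te, fs)
        mod <- train_plsda(Xtr, cc_tr$cohort$group, positive = positive,
                           folds = folds, component_grid = component_grid,
                           seed = seeds[si])
        ev <- evaluate_classifier(mod, Xte, cc_te$cohort$group)
        rows[[length(rows) + 1L]] <- data.frame(
          comparison = cmp, mode = mode, rep = r, ncomp = mod$ncomp,
          sensitivity = ev$sensitivity, specificity = ev$specificity,
          auc = ev$auc, n_features = nrow(fs$edges),
          fallback = isTRUE(fs$fallback), stringsAsFactors = FALSE
        )
      }
    }
  }
  metrics <- do.call(rbind, rows)
  summary <- stats::aggregate(
    metrics[, c("sensitivity", "specificity", "auc")],
    by = metrics[, c("comparison", "mode")], FUN = mean
  )
  comparison <- NULL
  if (all(c("key", "full") %in% modes)) {
    comparison <- do.call(rbind, lapply(names(comparisons), function(cmp) {
      kdf <- metrics[metrics$comparison == cmp & metrics$mode == "key", ]
      fdf <- metrics[metrics$comparison == cmp & metrics$mode == "full", ]
      if (nrow(kdf) < 2) return(NULL)
      cbind(comparison = cmp, compare_models(kdf, fdf))
    }))
  }
  out <- list(metrics = metrics, summary = summary, comparison = comparison)
  class(out) <- "classification_report"
  out
}

# Subset a cohort to subject row indices.
subset_subjects <- function(cc, idx) {
  out <- cc
  out$cohort <- cc$cohort[idx, , drop = FALSE]
  rownames(out$cohort) <- NULL
  out$connectomes <- cc$connectomes[as.character(out$cohort$subject_id)]
  out
}

#' @export
print.classification_report <- function(x, ...) {
  cat("PLS-DA classification report (means over repeats):\n")
  print(x$summary, row.names = FALSE)
  if (!is.null(x$comparison)) {
    cat("\nKey vs. full feature comparison (paired t):\n")
    print(x$comparison, row.names = FALSE)
  }
  invisible(x)
}
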