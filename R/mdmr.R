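# Multivariate distance matrix regression (MDMR) on per-region
# connectivity profiles: correlation distances between subjects,
# sum-of-squares decomposition, pseudo-F, covariate-adjusted permutation
# inference, and FDR control across regions.

#' Correlation distance between two connectivity vectors
#'
#' \eqn{d_{uv} = \sqrt{2 (1 - r_{uv})}} with \eqn{r_{uv}} the Pearson
#' correlation between the two vectors.  The distance is
#' Euclidean-embeddable and bounded in \eqn{[0, 2]}: identical profiles
#' give 0, uncorrelated ones \eqn{\sqrt 2}, exactly anti-correlated
#' ones 2.  If either vector has zero variance the correlation is
#' undefined; it is taken as 0 (d = \eqn{\sqrt 2}) and the result
#' carries a `"degenerate"` attribute.
#'
#' @param vec_u,vec_v Numeric vectors of equal length (>= 3).
#' @return Scalar distance in `[0, 2]`.
#' @export
correlation_distance <- function(vec_u, vec_v) {
  if (length(vec_u) != length(vec_v)) {
    stop("connectivity vectors differ in length (", length(vec_u),
         " vs ", length(vec_v), ")")
  }
  if (length(vec_u) < 3L) stop("connectivity vectors must have length >= 3")
  degenerate <- stats::sd(vec_u) == 0 || stats::sd(vec_v) == 0
  r <- if (degenerate) 0 else stats::cor(vec_u, vec_v)
  d <- sqrt(max(0, 2 * (1 - r)))
  if (degenerate) attr(d, "degenerate") <- TRUE
  d
}

#' Subject-space distance matrix for one seed region
#'
#' Extracts every subject's connectivity vector for the seed region and
#' computes all pairwise correlation distances, giving the
#' n-subjects-by-n-subjects distance matrix analyzed by MDMR.
#' Zero-variance vectors (e.g. isolated regions after thresholding) get
#' correlation 0 against every other subject; affected subject ids are
#' reported in the `"degenerate_subjects"` attribute.
#'
#' @param cc A `"connectome_cohort"` (or plain list of matrices).
#' @param seed_region Node index or label.
#' @return Symmetric matrix with zero diagonal, entries in `[0, 2]`,
#'   dimnames = subject ids.
#' @export
region_distance_matrix <- function(cc, seed_region) {
  mats <- if (inherits(cc, "connectome_cohort")) cc$connectomes else cc
  if (length(mats) < 3L) stop("at least 3 subjects are required")
  i <- resolve_node(mats[[1]], seed_region)
  X <- t(vapply(mats, function(m) m[i, -i], numeric(nrow(mats[[1]]) - 1L)))
  rownames(X) <- names(mats)
  dist_from_profiles(X)
}

# Correlation-distance matrix between the rows of a subject-by-feature
# profile matrix.  Zero-variance rows get r = 0 against everyone.
dist_from_profiles <- function(X) {
  sds <- apply(X, 1, stats::sd)
  degen <- sds == 0
  R <- matrix(0, nrow(X), nrow(X))
  ok <- !degen
  if (sum(ok) >= 2L) {
    R[ok, ok] <- suppressWarnings(stats::cor(t(X[ok, , drop = FALSE])))
  }
  diag(R) <- 1
  D <- 2 * (1 - R)
  D[D < 0] <- 0
  D <- sqrt(D)
  diag(D) <- 0
  dimnames(D) <- list(rownames(X), rownames(X))
  if (any(degen)) {
    attr(D, "degenerate_subjects") <- rownames(X)[degen]
  }
  D
}

#' Pseudo-F decomposition for grouped distances
#'
#' Distance-based ANOVA of a subject-space distance matrix:
#' \deqn{SS_T = \frac{1}{n} \sum_{u<v} d_{uv}^2, \qquad
#'       SS_W = \sum_g \frac{1}{n_g} \sum_{u<v \in g} d_{uv}^2,}
#' \eqn{SS_A = SS_T - SS_W}, and the pseudo-F statistic
#' \deqn{F = (n - 1)\, SS_A / SS_W.}
#' The within-group term generalizes additively to any number of
#' groups.  Significance is assessed by permutation, never against an F
#' distribution.
#'
#' @param D Symmetric distance matrix.
#' @param labels Group label per subject (factor or character).
#' @return List with `pseudo_F`, `SST`, `SSW`, `SSA`, `n`, `k`.  When
#'   `SSW == 0` the statistic is `Inf` and the result carries a
#'   `"zero_within"` flag.
#' @export
pseudo_f_groups <- function(D, labels) {
  labels <- droplevels(as.factor(labels))
  n <- nrow(D)
  stopifnot(length(labels) == n)
  if (any(table(labels) < 2)) stop("every group needs >= 2 members")
  D2 <- D^2
  sst <- sum(D2[upper.tri(D2)]) / n
  ssw <- 0
  for (g in levels(labels)) {
    idx <- which(labels == g)
    sub <- D2[idx, idx, drop = FALSE]
    ssw <- ssw + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ssa <- sst - ssw
  out <- list(
    pseudo_F = if (ssw == 0) Inf else (n - 1) * ssa / ssw,
    SST = sst, SSW = ssw, SSA = ssa,
    n = n, k = nlevels(labels)
  )
  if (ssw == 0) attr(out, "zero_within") <- TRUE
  out
}

#' Gower-center a distance matrix
#'
#' Transforms a squared-distance matrix into the doubly centered
#' inner-product (Gower) matrix \eqn{G = C A C}, \eqn{A_{uv} =
#' -d_{uv}^2/2}, \eqn{C = I - \mathbf{1}\mathbf{1}'/n}.  Rows and
#' columns of `G` sum to zero, \eqn{\mathrm{tr}(G) = SS_T}, and
#' projector traces of `G` recover the distance-ANOVA sums of squares,
#' which is the route by which covariates enter the model.
#'
#' @param D Symmetric distance matrix.
#' @return Centered inner-product matrix of the same dimension.
#' @export
gower_center <- function(D) {
  A <- -0.5 * D^2
  rm_ <- rowMeans(A)
  cm_ <- colMeans(A)
  A - outer(rm_, rep(1, ncol(A))) - outer(rep(1, nrow(A)), cm_) + mean(A)
}

# Hat (projection) matrix onto the column space of M, via QR.
hat_matrix <- function(M) {
  q <- qr(M)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}

# Build the covariate design Z = [1 | covariates] with factors expanded
# and constant columns dropped (recorded in attr "dropped").  Errors on
# collinear columns, naming them.
covariate_design <- function(covariates, n) {
  if (is.null(covariates) || (is.data.frame(covariates) && ncol(covariates) == 0)) {
    Z <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
    return(Z)
  }
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == n)
  if (anyNA(covariates)) stop("covariates contain missing values")
  Z <- stats::model.matrix(~ ., data = covariates)
  keep <- c(TRUE, apply(Z[, -1, drop = FALSE], 2, function(x) stats::var(x) > 0))
  dropped <- colnames(Z)[!keep]
  Z <- Z[, keep, drop = FALSE]
  q <- qr(Z)
  if (q$rank < ncol(Z)) {
    bad <- colnames(Z)[q$pivot[(q$rank + 1):ncol(Z)]]
    stop("covariate design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  if (length(dropped)) attr(Z, "dropped") <- dropped
  Z
}

#' Covariate-adjusted pseudo-F via projector traces
#'
#' Semi-partial distance-regression statistic: with `G` the Gower
#' matrix of `D`, `H_cov` the hat matrix of intercept + covariates and
#' `H_full` the hat matrix of covariates + group indicators,
#' \deqn{F_{ratio} = \frac{\mathrm{tr}(H_\Delta G)}{\mathrm{tr}((I - H_{full}) G)},
#'   \qquad H_\Delta = H_{full} - H_{cov}.}
#' With no covariates this reduces exactly to \eqn{SS_A / SS_W} of
#' [pseudo_f_groups()]; the reported `pseudo_F` is scaled by `(n - 1)`
#' so the two agree on that case.  Both scalings are strictly monotone
#' in each other, hence interchangeable under permutation.
#'
#' @param D Symmetric distance matrix.
#' @param labels Group labels.
#' @param covariates Optional data frame of nuisance covariates (e.g.
#'   age, sex, ApoE-4 status), one row per subject.
#' @return List with `pseudo_F` (`(n-1) *` the trace ratio), `f_ratio`,
#'   `SSA`, `SSW`, `SST`, and `dropped` (constant covariate columns
#'   removed).
#' @export
pseudo_f_adjusted <- function(D, labels, covariates = NULL) {
  labels <- droplevels(as.factor(labels))
  n <- nrow(D)
  stopifnot(length(labels) == n)
  G <- gower_center(D)
  Z <- covariate_design(covariates, n)
  Xg <- stats::model.matrix(~ labels)[, -1, drop = FALSE]
  H_cov <- hat_matrix(Z)
  H_full <- hat_matrix(cbind(Z, Xg))
  Hd <- H_full - H_cov
  Hr <- diag(n) - H_full
  ssa <- sum(Hd * G)
  ssw <- sum(Hr * G)
  list(
    pseudo_F = if (ssw == 0) Inf else (n - 1) * ssa / ssw,
    f_ratio = if (ssw == 0) Inf else ssa / ssw,
    SSA = ssa, SSW = ssw, SST = sum(diag(G)),
    dropped = attr(Z, "dropped")
  )
}

#' Permutation test for the (adjusted) pseudo-F
#'
#' Permutation p-value for the group effect on a subject-space distance
#' matrix, with the add-one convention
#' \eqn{p = (1 + \#\{F^\ast \ge F_{obs}\}) / (B + 1)} and ties counted
#' as extreme.  Without covariates, subject indices of the Gower matrix
#' are permuted (equivalently, group labels).  With covariates the
#' default is the Freedman–Lane scheme: the Gower matrix is residualized
#' on the covariate design (`G_res = R_z G R_z`), its subject indices
#' are permuted, and the statistic is recomputed with the original
#' projectors, so the covariate structure is held fixed while the
#' residual exchangeable structure is shuffled.  `scheme = "labels"`
#' instead permutes raw group labels and rebuilds the group projector
#' each time.
#'
#' @param D Symmetric distance matrix.
#' @param labels Group labels.
#' @param covariates Optional covariate data frame.
#' @param B Number of permutations (>= 99 unless `exhaustive`).
#' @param seed Integer seed for the permutation stream.
#' @param scheme `"freedman_lane"` (default) or `"labels"`.
#' @param exhaustive If `TRUE`, enumerate all `n!` permutations
#'   (feasible for n <= 8) and return the exact rank-based p-value
#'   `#\{F* >= F_obs\} / n!` (identity included); `B` and `seed` are
#'   ignored.
#' @return List with `p`, `F_obs` (reported on the `(n-1)`-scaled
#'   pseudo-F scale), `B`, and the vector `F_perm` of permuted
#'   statistics (ratio scale).
#' @export
mdmr_permutation_test <- function(D, labels, covariates = NULL, B = 5000,
                                  seed = 1L,
                                  scheme = c("freedman_lane", "labels"),
                                  exhaustive = FALSE) {
  scheme <- match.arg(scheme)
  labels <- droplevels(as.factor(labels))
  n <- nrow(D)
  if (!exhaustive && B < 99) stop("B must be >= 99")
  obs <- pseudo_f_adjusted(D, labels, covariates)
  G <- gower_center(D)
  Z <- covariate_design(covariates, n)
  Xg <- stats::model.matrix(~ labels)[, -1, drop = FALSE]
  H_cov <- hat_matrix(Z)
  H_full <- hat_matrix(cbind(Z, Xg))
  Hd <- H_full - H_cov
  Hr <- diag(n) - H_full
  no_cov <- ncol(Z) == 1L

  G_base <- if (no_cov || scheme == "labels") {
    G
  } else {
    Rz <- diag(n) - H_cov
    Rz %*% G %*% Rz
  }

  stat_for_perm <- function(p) {
    if (scheme == "labels" && !no_cov) {
      Hf_p <- hat_matrix(cbind(Z, Xg[p, , drop = FALSE]))
      num <- sum((Hf_p - H_cov) * G)
      den <- sum((diag(n) - Hf_p) * G)
    } else {
      Gp <- G_base[p, p]
      num <- sum(Hd * Gp)
      den <- sum(Hr * Gp)
    }
    if (den == 0) Inf else num / den
  }

  if (exhaustive) {
    perms <- all_permutations(n)
    F_perm <- vapply(perms, stat_for_perm, numeric(1))
    p <- mean(F_perm >= obs$f_ratio - 1e-12)
    return(list(p = p, F_obs = obs$pseudo_F, B = length(perms), F_perm = F_perm))
  }

  F_perm <- with_seed_(seed, {
    vapply(seq_len(B), function(b) stat_for_perm(sample.int(n)), numeric(1))
  })
  p <- (1 + sum(F_perm >= obs$f_ratio - 1e-12)) / (B + 1)
  list(p = p, F_obs = obs$pseudo_F, B = B, F_perm = F_perm)
}

# All permutations of 1..n as a list (n! entries; use only for small n).
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    for (s in sub) {
      k <- k + 1L
      out[[k]] <- c(i, s + (s >= i))
    }
  }
  out
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up q-values over a family of permutation p-values (here the 90
#' regional tests of one comparison).  Thin wrapper over
#' [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return q-values in the original order.
#' @export
fdr_correct <- function(p_values) {
  stopifnot(all(p_values > 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH")
}

#' Run MDMR across all regions and comparisons
#'
#' The full connectome-wide association scan: for each requested group
#' comparison and each region, compute the subject-space correlation
#' distance matrix, the covariate-adjusted pseudo-F, a permutation
#' p-value, and Benjamini-Hochberg q-values across regions.
#'
#' @param cc A `"connectome_cohort"`.
#' @param comparisons Named list of group-label vectors, e.g.
#'   `list(CN_vs_AD = c("CN", "AD"), three_group = c("CN", "cMCI", "AD"))`.
#' @param covariates Character vector of cohort columns to adjust for
#'   (default `c("age", "sex", "apoe4")`); use `NULL` for none.
#' @param B Permutations per region (default 5000).
#' @param seed Master seed; per-(comparison, region) seeds are derived
#'   deterministically from it.
#' @param scheme Permutation scheme, see [mdmr_permutation_test()].
#' @param regions Node indices to test (default all).
#' @return Named list (one element per comparison) of data frames with
#'   columns `region`, `region_label`, `pseudo_F`, `p_perm`, `q_fdr`,
#'   `n_perm`, `flag`; class `"mdmr_result"`.
#' @export
run_mdmr <- function(cc, comparisons,
                     covariates = c("age", "sex", "apoe4"),
                     B = 5000, seed = 1L,
                     scheme = c("freedman_lane", "labels"),
                     regions = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(cc, "connectome_cohort"))
  if (is.null(names(comparisons)) || any(names(comparisons) == "")) {
    stop("comparisons must be a named list")
  }
  n_nodes <- nrow(cc$connectomes[[1]])
  if (is.null(regions)) regions <- seq_len(n_nodes)
  labels_vocab <- rownames(cc$connectomes[[1]])
  seeds <- derive_seeds(seed, length(comparisons) * length(regions))
  out <- list()
  si <- 0L
  for (cmp in names(comparisons)) {
    sub <- subset_cohort(cc, comparisons[[cmp]])
    cov_df <- if (length(covariates)) sub$cohort[, covariates, drop = FALSE] else NULL
    res <- data.frame(region = regions,
                      region_label = labels_vocab[regions],
                      pseudo_F = NA_real_, p_perm = NA_real_,
                      q_fdr = NA_real_, n_perm = B, flag = "",
                      stringsAsFactors = FALSE)
    for (ri in seq_along(regions)) {
      si <- si + 1L
      D <- region_distance_matrix(sub, regions[ri])
      pt <- mdmr_permutation_test(D, sub$cohort$group, cov_df, B = B,
                                  seed = seeds[si], scheme = scheme)
      res$pseudo_F[ri] <- pt$F_obs
      res$p_perm[ri] <- pt$p
      dg <- attr(D, "degenerate_subjects")
      if (!is.null(dg)) res$flag[ri] <- "degenerate_vectors"
    }
    res$q_fdr <- fdr_correct(res$p_perm)
    out[[cmp]] <- res
  }
  class(out) <- "mdmr_result"
  out
}

# Deterministic stream of sub-seeds from one master seed.
derive_seeds <- function(master, n) {
  with_seed_(master, sample.int(.Machine$integer.max - 1L, n))
}
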