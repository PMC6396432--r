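# Synthetic connectome-cohort generator.  Emulates a cross-sectional
# Alzheimer's staging cohort (CN / sMCI / cMCI / AD) of weighted
# structural connectomes: a shared population template of heavy-tailed
# nonnegative edge weights, per-subject multiplicative noise, planted
# connectivity-PATTERN alterations at chosen seed regions whose
# magnitude grows with disease stage, and demographic covariates.

GROUP_LEVELS <- c("CN", "sMCI", "cMCI", "AD")

default_covariate_model <- function() {
  data.frame(
    group       = GROUP_LEVELS,
    age_mean    = c(74.5, 74.5, 76.5, 74.6),
    age_sd      = c(5.9, 8.4, 7.3, 7.7),
    female_prop = c(24 / 46, 18 / 48, 11 / 27, 17 / 40),
    apoe4_prob  = c(0.00, 0.167, 0.222, 0.15),
    stringsAsFactors = FALSE
  )
}

#' Specification of a synthetic connectome cohort
#'
#' Bundles and validates all parameters of the generator.  Defaults
#' emulate a four-group Alzheimer's staging cohort: 90 network nodes,
#' group sizes 46/48/27/40 (CN/sMCI/cMCI/AD), demographics matched
#' across groups, and an ApoE-4 carrier rate rising from 0 in controls.
#'
#' @param n_nodes Number of network nodes (default 90).
#' @param group_sizes Named integer vector of subjects per diagnostic
#'   group; names from `CN, sMCI, cMCI, AD`; every size must be >= 2 so
#'   within-group sums of squares are defined.
#' @param planted_seeds Integer node indices whose connectivity pattern
#'   is altered in affected groups (may be empty).
#' @param effect_size Nonnegative scale `e` of the planted alteration at
#'   the cMCI stage; stages multiply it via `stage_effects`.  Default 2,
#'   calibrated by power simulation so that planted seeds are reliably
#'   recovered at reduced problem sizes (see the package vignette).
#' @param stage_effects Named multipliers per group applied to
#'   `effect_size`; default `c(CN = 0, sMCI = 0, cMCI = 1, AD = 2)`:
#'   controls unaffected by definition, the stable-MCI stage shows no
#'   pattern alteration, and the effect doubles from converting MCI to
#'   AD.  Must be 0 for CN and nondecreasing CN -> cMCI -> AD.
#' @param base_density Fraction of structurally present edges in the
#'   population template (default 0.10; a 5 percent density threshold
#'   downstream then selects among present edges).
#' @param edge_weight_scale Log-normal location (median) of template
#'   edge weights.
#' @param edge_sdlog Log-normal scale of template edge weights (spread
#'   across edges; heavy-tailed like streamline-count-derived weights).
#' @param subject_sdlog Log-normal scale of per-subject multiplicative
#'   noise around the template.
#' @param amp_frac Fraction of a planted seed's present edges whose
#'   weight is attenuated by `1 / (1 + e)` in affected subjects — the
#'   amplitude-decline component of the alteration.
#' @param reroute_frac Fraction (relative to the seed's present-edge
#'   count) of previously absent partners included in the rerouting
#'   blend: the seed's remaining present-edge weights move a share
#'   `e / (1 + e)` toward a rank-reversing reassignment of themselves
#'   over these slots, so weight migrates between partners and the
#'   connection pattern — not only its amplitude — changes.
#' @param covariate_model Data frame with columns `group`, `age_mean`,
#'   `age_sd`, `female_prop`, `apoe4_prob`; defaults follow the matched
#'   staging-cohort demographics above.
#' @param confounded If `TRUE`, age is shifted upward with disease
#'   stage (+3 years per stage) to exercise covariate adjustment.
#' @param rng_seed Integer master seed; all generator randomness is
#'   derived from it.
#' @return Object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_nodes = 90L,
                           group_sizes = c(CN = 46L, sMCI = 48L, cMCI = 27L, AD = 40L),
                           planted_seeds = integer(0),
                           effect_size = 2,
                           stage_effects = c(CN = 0, sMCI = 0, cMCI = 1, AD = 2),
                           base_density = 0.10,
                           edge_weight_scale = 1,
                           edge_sdlog = 1,
                           subject_sdlog = 0.4,
                           amp_frac = 0.30,
                           reroute_frac = 0.15,
                           covariate_model = default_covariate_model(),
                           confounded = FALSE,
                           rng_seed = 1L) {
  if (n_nodes < 4) stop("n_nodes must be at least 4")
  if (is.null(names(group_sizes)) ||
      !all(names(group_sizes) %in% GROUP_LEVELS)) {
    stop("group_sizes must be named with labels among: ",
         paste(GROUP_LEVELS, collapse = ", "))
  }
  if (any(group_sizes < 2)) {
    stop("every group size must be >= 2 (within-group pairs required)")
  }
  if (!is.numeric(effect_size) || effect_size < 0) {
    stop("effect_size must be nonnegative")
  }
  se <- stage_effects[GROUP_LEVELS]
  names(se) <- GROUP_LEVELS
  se[is.na(se)] <- 0
  if (se[["CN"]] != 0) stop("stage effect for CN must be 0 by definition")
  if (any(se < 0)) stop("stage effects must be nonnegative")
  prog <- se[c("CN", "cMCI", "AD")]
  if (is.unsorted(prog)) {
    stop("stage effects must be nondecreasing across CN -> cMCI -> AD")
  }
  if (base_density <= 0 || base_density > 1) stop("base_density must be in (0, 1]")
  if (edge_weight_scale <= 0) stop("edge_weight_scale must be positive")
  planted_seeds <- as.integer(planted_seeds)
  if (any(planted_seeds < 1 | planted_seeds > n_nodes)) {
    stop("planted_seeds out of node range")
  }
  structure(list(
    n_nodes = as.integer(n_nodes),
    group_sizes = group_sizes,
    planted_seeds = planted_seeds,
    effect_size = effect_size,
    stage_effects = se,
    base_density = base_density,
    edge_weight_scale = edge_weight_scale,
    edge_sdlog = edge_sdlog,
    subject_sdlog = subject_sdlog,
    amp_frac = amp_frac,
    reroute_frac = reroute_frac,
    covariate_model = covariate_model,
    confounded = confounded,
    rng_seed = as.integer(rng_seed)
  ), class = "synthetic_spec")
}

# Evaluate code under a given seed without disturbing the caller's RNG.
with_seed_ <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generate a synthetic cohort of structural connectomes
#'
#' Draws a population template (present edges at `base_density`,
#' log-normal weights), then per subject multiplies template weights by
#' log-normal noise.  For each planted seed region a fixed alteration
#' plan is drawn once per cohort — an attenuated edge subset plus a
#' rerouting blend that migrates weight between the seed's partners,
#' including previously absent ones — and applied to every subject of
#' an affected group with stage-dependent magnitude, so the alteration
#' is a group-level connectivity-pattern difference.  With
#' `effect_size = 0` the group label is independent of the connectome
#' distribution.
#'
#' @param spec A [synthetic_spec()].
#' @return Object of class `"connectome_cohort"`: a list with
#'   `cohort` (data frame: `subject_id`, `group`, `age`, `sex`,
#'   `apoe4`), `connectomes` (named list of symmetric matrices),
#'   `planted` (per-seed alteration plan), and `spec`.  Regeneration
#'   with the same `rng_seed` is bit-identical.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed_(spec$rng_seed, {
    n <- spec$n_nodes
    labels <- node_labels(n)
    pairs <- upper_triangle_pairs(n)
    P <- nrow(pairs)
    present <- which(stats::runif(P) < spec$base_density)
    if (length(present) < 2L) stop("base_density too low: template nearly empty")
    tmpl <- numeric(P)
    tmpl[present] <- stats::rlnorm(length(present),
                                   meanlog = log(spec$edge_weight_scale),
                                   sdlog = spec$edge_sdlog)

    plan <- plant_alteration_plan(spec, pairs, present, tmpl)

    groups <- names(spec$group_sizes)
    cohort <- data.frame(
      subject_id = character(0), group = character(0),
      age = numeric(0), sex = character(0), apoe4 = integer(0),
      stringsAsFactors = FALSE
    )
    connectomes <- list()
    cm <- spec$covariate_model
    stage_idx <- match(groups, GROUP_LEVELS)
    sid <- 0L
    for (gi in seq_along(groups)) {
      g <- groups[gi]
      ng <- spec$group_sizes[[g]]
      e <- spec$stage_effects[[g]] * spec$effect_size
      row <- cm[match(g, cm$group), ]
      if (any(is.na(row))) row <- cm[1, ]
      age_shift <- if (spec$confounded) 3 * (stage_idx[gi] - 1L) else 0
      for (s in seq_len(ng)) {
        sid <- sid + 1L
        id <- sprintf("S%03d", sid)
        wp <- tmpl
        wp[present] <- wp[present] *
          exp(stats::rnorm(length(present), 0, spec$subject_sdlog))
        wp <- apply_plan(wp, plan, e)
        w <- matrix(0, n, n, dimnames = list(labels, labels))
        w[cbind(pairs[, 1], pairs[, 2])] <- wp
        w <- w + t(w)
        connectomes[[id]] <- w
        cohort <- rbind(cohort, data.frame(
          subject_id = id, group = g,
          age = stats::rnorm(1, row$age_mean + age_shift, row$age_sd),
          sex = if (stats::runif(1) < row$female_prop) "F" else "M",
          apoe4 = stats::rbinom(1, 1, row$apoe4_prob),
          stringsAsFactors = FALSE
        ))
      }
    }
    cohort$group <- factor(cohort$group, levels = GROUP_LEVELS)
    cohort$group <- droplevels(cohort$group)
    structure(list(cohort = cohort, connectomes = connectomes,
                   planted = plan, spec = spec),
              class = "connectome_cohort")
  })
}

# Draw, once per cohort, the per-seed alteration plan.  Two
# ingredients, both fixed per cohort so they constitute a group-level
# pattern difference:
#   * an attenuated subset (amp_frac of the seed's present edges)
#     whose weights are divided by (1 + e) — the amplitude-decline
#     component, bounded so it cannot create leverage outliers in a
#     partner's profile;
#   * a rerouting permutation: the seed's remaining present-edge
#     weights are blended toward a fixed shuffled re-assignment of
#     themselves over the seed's edge slots, including a few
#     previously absent partners (reroute_frac of the present count),
#     so weight migrates between partners and the seed's topology
#     changes.
# The blend share is e/(1+e), 0 at e = 0.  Because the shuffle moves
# *every* rerouted coordinate of the seed coherently while each
# partner region sees only a single noise-scale edge change, the
# pattern alteration concentrates at the seed.  Indices refer to rows
# of the upper-triangle pair table.
plant_alteration_plan <- function(spec, pairs, present, tmpl) {
  plan <- list()
  for (r in spec$planted_seeds) {
    touches <- present[pairs[present, 1] == r | pairs[present, 2] == r]
    if (length(touches) < 2L) {
      plan[[as.character(r)]] <- list(seed = r, amplified = integer(0),
                                      slots = integer(0), sigma = integer(0))
      next
    }
    n_amp <- max(1L, round(spec$amp_frac * length(touches)))
    n_new <- max(1L, round(spec$reroute_frac * length(touches)))
    shuffled <- sample(touches)
    amp <- shuffled[seq_len(min(n_amp, length(shuffled)))]
    rer <- setdiff(shuffled, amp)
    touches_all <- which(pairs[, 1] == r | pairs[, 2] == r)
    absent <- setdiff(touches_all, present)
    new_slots <- if (length(absent)) sample(absent, min(n_new, length(absent)))
                 else integer(0)
    slots <- c(rer, new_slots)
    # rank-reversing assignment: the strongest rerouted weight migrates
    # to the weakest slot and vice versa — a maximal, reproducible
    # re-patterning of the seed profile (a random shuffle can draw
    # near-identity assignments and plant almost no pattern change)
    sigma <- seq_along(slots)
    if (length(slots) >= 2L) {
      tw <- tmpl[slots]
      sigma[order(tw, decreasing = TRUE)] <- order(tw)
    }
    plan[[as.character(r)]] <- list(seed = r, amplified = amp,
                                    slots = slots, sigma = sigma)
  }
  plan
}

# Apply the alteration plan to one subject's upper-triangle weight
# vector at stage magnitude e (no-op when e == 0).
apply_plan <- function(wp, plan, e) {
  if (e == 0 || !length(plan)) return(wp)
  lambda <- e / (1 + e)
  for (pl in plan) {
    if (length(pl$amplified)) {
      wp[pl$amplified] <- wp[pl$amplified] / (1 + e)
    }
    if (length(pl$slots) >= 2L) {
      v <- wp[pl$slots]
      wp[pl$slots] <- (1 - lambda) * v + lambda * v[pl$sigma]
    }
  }
  wp
}

# All upper-triangle pair indices altered by a seed's plan, and the
# partner nodes involved (useful for recovery checks).  Only slots the
# shuffle actually moves count as altered.
altered_edges <- function(plan_entry, pairs) {
  moved <- plan_entry$slots[plan_entry$sigma != seq_along(plan_entry$sigma)]
  idx <- c(plan_entry$amplified, moved)
  partners <- setdiff(unique(as.vector(pairs[idx, , drop = FALSE])),
                      plan_entry$seed)
  list(pair_index = idx, partners = partners)
}

#' Generate a streamline tractography summary
#'
#' Produces the aggregate quantities that feed [compute_edge_weight()]
#' without running tractography: per node pair a streamline count and a
#' mean streamline length, plus per-node surface areas.  The implied
#' edge-weight matrix (all of a pair's streamlines at the pair's mean
#' length) is returned alongside, so feeding the summary back through
#' [compute_edge_weight()] reproduces it exactly.
#'
#' @param spec A [synthetic_spec()]; only its template-level fields are
#'   used.
#' @return List with matrices `counts` (nonnegative integers) and
#'   `mean_lengths` (positive; `NA` where no streamlines), vector
#'   `surfaces` (positive, per node), and the implied `weights` matrix.
#' @export
generate_streamline_summary <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed_(spec$rng_seed + 1L, {
    n <- spec$n_nodes
    labels <- node_labels(n)
    pairs <- upper_triangle_pairs(n)
    P <- nrow(pairs)
    present <- which(stats::runif(P) < spec$base_density)
    counts_v <- integer(P)
    counts_v[present] <- 1L + stats::rpois(length(present), 19)
    len_v <- rep(NA_real_, P)
    len_v[present] <- stats::runif(length(present), 20, 120)
    surfaces <- stats::runif(n, 800, 1600)
    names(surfaces) <- labels

    mk <- function(v, fill = 0) {
      m <- matrix(fill, n, n, dimnames = list(labels, labels))
      m[cbind(pairs[, 1], pairs[, 2])] <- v
      m[cbind(pairs[, 2], pairs[, 1])] <- v
      m
    }
    counts <- mk(counts_v)
    mean_lengths <- mk(len_v, fill = NA_real_)
    diag(mean_lengths) <- NA_real_
    wv <- numeric(P)
    wv[present] <- 2 / (surfaces[pairs[present, 1]] + surfaces[pairs[present, 2]]) *
      counts_v[present] / len_v[present]
    weights <- mk(wv)
    list(counts = counts, mean_lengths = mean_lengths,
         surfaces = surfaces, weights = weights)
  })
}

#' Assemble a connectome cohort from user data
#'
#' @param cohort Data frame with columns `subject_id`, `group`, `age`,
#'   `sex`, `apoe4`.
#' @param connectomes Named list of connectivity matrices keyed by
#'   `subject_id`.
#' @return A `"connectome_cohort"` object.
#' @export
connectome_cohort <- function(cohort, connectomes) {
  req <- c("subject_id", "group", "age", "sex", "apoe4")
  miss <- setdiff(req, names(cohort))
  if (length(miss)) stop("cohort is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(cohort$subject_id)) stop("duplicate subject_id in cohort")
  bad <- setdiff(unique(as.character(cohort$group)), GROUP_LEVELS)
  if (length(bad)) {
    stop("unknown group label(s) ", paste(bad, collapse = ", "),
         "; allowed: ", paste(GROUP_LEVELS, collapse = ", "))
  }
  if (!all(cohort$subject_id %in% names(connectomes))) {
    stop("every subject_id needs a matching connectome")
  }
  connectomes <- connectomes[as.character(cohort$subject_id)]
  for (w in connectomes) validate_connectome(w)
  cohort$group <- droplevels(factor(cohort$group, levels = GROUP_LEVELS))
  structure(list(cohort = cohort, connectomes = connectomes,
                 planted = list(), spec = NULL),
            class = "connectome_cohort")
}

#' Subset a cohort to selected diagnostic groups
#'
#' @param cc A `"connectome_cohort"`.
#' @param groups Character vector of group labels to keep.
#' @return A `"connectome_cohort"` restricted to those subjects, group
#'   factor releveled to the kept groups.
#' @export
subset_cohort <- function(cc, groups) {
  stopifnot(inherits(cc, "connectome_cohort"))
  miss <- setdiff(groups, levels(cc$cohort$group))
  if (length(miss)) stop("group(s) absent from cohort: ", paste(miss, collapse = ", "))
  keep <- cc$cohort$group %in% groups
  out <- cc
  out$cohort <- cc$cohort[keep, , drop = FALSE]
  rownames(out$cohort) <- NULL
  out$cohort$group <- factor(as.character(out$cohort$group),
                             levels = intersect(GROUP_LEVELS, groups))
  out$connectomes <- cc$connectomes[as.character(out$cohort$subject_id)]
  out
}

#' @export
print.connectome_cohort <- function(x, ...) {
  cat("Connectome cohort:", nrow(x$cohort), "subjects,",
      nrow(x$connectomes[[1]]), "nodes\n")
  print(table(x$cohort$group))
  if (length(x$planted)) {
    cat("Planted seed regions:",
        paste(vapply(x$planted, function(p) p$seed, 0L), collapse = ", "), "\n")
  }
  invisible(x)
}
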