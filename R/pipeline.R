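# End-to-end driver: simulate -> build (threshold) -> mdmr -> posthoc
# -> classify, with one master seed, per-stage derived seeds, and a
# JSON run manifest sufficient for exact replay.

#' Configuration of a pipeline run
#'
#' Validates and bundles every tunable of the end-to-end analysis.
#'
#' @param out_dir Output directory.
#' @param spec A [synthetic_spec()] (for the simulate stage), or `NULL`
#'   when `input_dir` provides real data.
#' @param input_dir Directory with `cohort.csv` + `matrices/` to load
#'   instead of simulating.
#' @param stages Stages to run, subset of
#'   `c("simulate", "build", "mdmr", "posthoc", "classify")`.
#' @param density Density threshold for the build stage (fraction in
#'   (0, 1]).
#' @param comparisons Named list of group sets for MDMR.
#' @param class_comparisons Named list of binary group pairs for
#'   classification.
#' @param covariates Covariate columns to adjust for.
#' @param B Permutations for MDMR and strength tests.
#' @param B_delta Randomizations for delta effect sizes.
#' @param seed_p_threshold Seed-selection p threshold for post-hoc and
#'   key features.
#' @param q_threshold FDR threshold used when reporting significant
#'   regions.
#' @param k_top Top connections per seed.
#' @param repeats,folds,test_fraction Classification protocol
#'   parameters.
#' @param master_seed Integer master seed; all stage seeds derive from
#'   it.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(out_dir,
                       spec = synthetic_spec(),
                       input_dir = NULL,
                       stages = c("simulate", "build", "mdmr", "posthoc", "classify"),
                       density = 0.05,
                       comparisons = list(CN_vs_sMCI = c("CN", "sMCI"),
                                          CN_vs_cMCI = c("CN", "cMCI"),
                                          CN_vs_AD = c("CN", "AD"),
                                          CN_cMCI_AD = c("CN", "cMCI", "AD")),
                       class_comparisons = list(CN_vs_cMCI = c("CN", "cMCI"),
                                                CN_vs_AD = c("CN", "AD")),
                       covariates = c("age", "sex", "apoe4"),
                       B = 5000, B_delta = 100,
                       seed_p_threshold = 0.001, q_threshold = 0.05,
                       k_top = 5, repeats = 5, folds = 5,
                       test_fraction = 0.2, master_seed = 1L) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  for (nm in c("seed_p_threshold", "q_threshold", "test_fraction")) {
    v <- get(nm)
    if (v <= 0 || v >= 1) stop(nm, " must be in (0, 1)")
  }
  if (B < 99 || B_delta < 50 || k_top < 1 || repeats < 1 || folds < 2) {
    stop("invalid counts in configuration")
  }
  if ("simulate" %in% stages && is.null(spec)) stop("simulate stage needs a spec")
  if (!"simulate" %in% stages && is.null(input_dir)) {
    stop("either the simulate stage or an input_dir is required")
  }
  rm(nm, v)
  structure(as.list(environment()), class = "run_config")
}

#' Run the configured pipeline
#'
#' Executes the requested stages in order, writes all result tables
#' (TSV) plus a JSON manifest to `out_dir`, and returns the in-memory
#' results.  All randomness derives from `master_seed`; result tables
#' from two runs with an identical configuration are byte-identical.
#'
#' @param config A [run_config()].
#' @return List with (depending on stages) `cohort_raw`, `cohort`,
#'   `mdmr`, `seeds`, `effects`, `strengths`, `strength_tests`,
#'   `classification`, `manifest`; invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_seed <- stats::setNames(
    derive_seeds(config$master_seed, 5L),
    c("simulate", "build", "mdmr", "posthoc", "classify")
  )
  warnings_log <- character(0)
  res <- list()

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- simulate / load -------------------------------------------------
  cc <- run_stage("simulate", {
    if ("simulate" %in% config$stages) {
      spec <- config$spec
      spec$rng_seed <- stage_seed[["simulate"]]
      out <- generate_cohort(spec)
      write_cohort_dir(out, file.path(config$out_dir, "simulated"))
      out
    } else {
      read_cohort_dir(config$input_dir)
    }
  })
  res$cohort_raw <- cc

  # --- build: density thresholding ------------------------------------
  if ("build" %in% config$stages) {
    cc <- run_stage("build", {
      out <- cc
      out$connectomes <- lapply(cc$connectomes, function(w) {
        tw <- apply_density_threshold(w, config$density)
        if (isTRUE(attr(tw, "tie_at_threshold"))) {
          warnings_log <<- c(warnings_log, "tie_at_density_threshold")
        }
        tw
      })
      out
    })
  }
  res$cohort <- cc

  # --- mdmr ------------------------------------------------------------
  if ("mdmr" %in% config$stages) {
    res$mdmr <- run_stage("mdmr", {
      m <- run_mdmr(cc, config$comparisons, covariates = config$covariates,
                    B = config$B, seed = stage_seed[["mdmr"]])
      for (cmp in names(m)) {
        write_tsv(m[[cmp]], file.path(config$out_dir, paste0("mdmr_", cmp, ".tsv")))
      }
      m
    })
  }

  # --- posthoc ---------------------------------------------------------
  if ("posthoc" %in% config$stages) {
    run_stage("posthoc", {
      sel_table <- res$mdmr[[length(res$mdmr)]]  # last comparison: multi-group scan
      seeds_sel <- sel_table$region[sel_table$p_perm < config$seed_p_threshold]
      if (!length(seeds_sel)) {
        warnings_log <- c(warnings_log, "no_seed_below_threshold")
        seeds_sel <- sel_table$region[order(sel_table$p_perm)][1]
      }
      sel_groups <- config$comparisons[[length(config$comparisons)]]
      sub <- subset_cohort(cc, sel_groups)
      eff <- do.call(rbind, lapply(seq_along(seeds_sel), function(ii) {
        delta_effect_size(sub, seeds_sel[ii], covariates = config$covariates,
                          B_delta = config$B_delta,
                          seed = stage_seed[["posthoc"]] + ii)
      }))
      top <- top_k_connections(eff, k = config$k_top)
      strengths <- nodal_strength_table(cc, seeds_sel)
      stests <- do.call(rbind, lapply(seeds_sel, function(nd) {
        glm_p <- strength_group_glm(strengths, cc$cohort, nd,
                                    covariates = config$covariates)$p
        prs <- utils::combn(levels(cc$cohort$group), 2, simplify = FALSE)
        pw <- vapply(prs, function(pr) {
          pairwise_strength_permutation(strengths, cc$cohort, nd, pr,
                                        covariates = config$covariates,
                                        B = config$B,
                                        seed = stage_seed[["posthoc"]] + nd)$p
        }, numeric(1))
        data.frame(node = nd,
                   node_label = rownames(cc$connectomes[[1]])[nd],
                   glm_p = glm_p,
                   t(stats::setNames(pw, vapply(prs, paste, "", collapse = "_vs_"))),
                   check.names = FALSE, stringsAsFactors = FALSE)
      }))
      res$seeds <- seeds_sel
      res$effects <- top
      res$strengths <- strengths
      res$strength_tests <- stests
      write_tsv(eff, file.path(config$out_dir, "posthoc_effects_all.tsv"))
      write_tsv(top, file.path(config$out_dir, "posthoc_top_connections.tsv"))
      write_tsv(strengths, file.path(config$out_dir, "nodal_strengths.tsv"))
      write_tsv(stests, file.path(config$out_dir, "strength_group_tests.tsv"))
      # radar-chart-ready per-group mean connectivity along top-k axes
      radar <- radar_table(sub, top)
      write_tsv(radar, file.path(config$out_dir, "radar_axes.tsv"))
    })
  }

  # --- classify --------------------------------------------------------
  if ("classify" %in% config$stages) {
    res$classification <- run_stage("classify", {
      rep_ <- run_classification(
        cc, comparisons = config$class_comparisons,
        repeats = config$repeats, folds = config$folds,
        test_fraction = config$test_fraction, covariates = config$covariates,
        B = config$B, B_delta = config$B_delta,
        seed_p = config$seed_p_threshold, k = config$k_top,
        seed = stage_seed[["classify"]]
      )
      write_tsv(rep_$metrics, file.path(config$out_dir, "classification_metrics.tsv"))
      write_tsv(rep_$summary, file.path(config$out_dir, "classification_summary.tsv"))
      if (!is.null(rep_$comparison)) {
        write_tsv(rep_$comparison,
                  file.path(config$out_dir, "classification_key_vs_full.tsv"))
      }
      rep_
    })
  }

  # --- manifest --------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("mdmrnet")),
    timestamp = format(Sys.time(), tz = "UTC"),
    master_seed = config$master_seed,
    stage_seeds = as.list(stage_seed[config$stages]),
    stages = config$stages,
    density = config$density,
    B = config$B, B_delta = config$B_delta,
    covariates = config$covariates,
    node_labels = rownames(cc$connectomes[[1]]),
    warnings = warnings_log
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}

# Per-group mean connectivity along the top-k axes of each seed
# (radar-chart-ready).
radar_table <- function(cc, top) {
  do.call(rbind, lapply(seq_len(nrow(top)), function(r) {
    i <- top$seed[r]; j <- top$partner[r]
    vals <- vapply(cc$connectomes, function(w) w[i, j], 0)
    agg <- tapply(vals, cc$cohort$group, mean)
    data.frame(seed_label = top$seed_label[r],
               partner_label = top$partner_label[r],
               group = names(agg), mean_weight = as.numeric(agg),
               stringsAsFactors = FALSE)
  }))
}
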