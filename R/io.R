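# Plain-text I/O: per-subject connectivity matrices (CSV matrix or
# long-format TSV edge list), cohort tables, and result tables.
# Comma-separated with header for matrices/cohorts, tab-separated for
# results; UTF-8, '.' decimal.

#' Read a connectivity matrix
#'
#' Accepts either a square labeled CSV matrix or a long-format TSV edge
#' list with columns `node_i`, `node_j`, `weight` (node labels or
#' 1-based indices; omitted pairs are zero).  Input is validated:
#' asymmetry within `1e-9` is symmetrized by averaging, larger
#' asymmetry is an error; negative weights are errors naming the cell.
#'
#' @param path File path (`.csv` matrix, `.tsv`/`.txt` edge list).
#' @param labels Expected node vocabulary; defaults to AAL-90 when the
#'   matrix has 90 unlabeled rows.  A labeled matrix mismatching the
#'   vocabulary is an error.
#' @return Validated connectome matrix.
#' @export
read_connectome <- function(path, labels = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, check.names = FALSE)
    first_is_label <- !is.numeric(df[[1]])
    rn <- if (first_is_label) df[[1]] else NULL
    if (first_is_label) df <- df[, -1, drop = FALSE]
    w <- as.matrix(df)
    if (nrow(w) != ncol(w)) stop("matrix in ", path, " is not square")
    if (!is.null(rn)) rownames(w) <- rn
    if (is.null(rownames(w))) rownames(w) <- colnames(w)
  } else {
    el <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("node_i", "node_j", "weight")
    if (!all(need %in% names(el))) {
      stop("edge list must have columns: ", paste(need, collapse = ", "))
    }
    if (is.null(labels)) {
      labs <- sort(unique(c(as.character(el$node_i), as.character(el$node_j))))
      if (suppressWarnings(all(!is.na(as.integer(labs))))) {
        labs <- node_labels(max(as.integer(labs)))
        el$node_i <- as.integer(el$node_i)
        el$node_j <- as.integer(el$node_j)
      }
    } else {
      labs <- labels
    }
    n <- length(labs)
    w <- matrix(0, n, n, dimnames = list(labs, labs))
    i <- if (is.numeric(el$node_i)) el$node_i else match(el$node_i, labs)
    j <- if (is.numeric(el$node_j)) el$node_j else match(el$node_j, labs)
    if (anyNA(i) || anyNA(j)) stop("edge list refers to unknown node labels")
    for (k in seq_along(i)) {
      prev <- w[i[k], j[k]]
      if (prev != 0 && abs(prev - el$weight[k]) > 1e-9) {
        stop(sprintf("inconsistent duplicate edge (%s, %s): %g vs %g",
                     el$node_i[k], el$node_j[k], prev, el$weight[k]))
      }
      w[i[k], j[k]] <- el$weight[k]
      w[j[k], i[k]] <- el$weight[k]
    }
  }
  storage.mode(w) <- "double"
  asym <- max(abs(w - t(w)))
  if (asym > 1e-9) {
    bad <- which(abs(w - t(w)) == asym, arr.ind = TRUE)[1, ]
    stop(sprintf("matrix asymmetric beyond tolerance at [%d, %d] (|diff| = %g)",
                 bad[1], bad[2], asym))
  }
  w <- (w + t(w)) / 2
  diag(w) <- 0
  if (!is.null(labels)) {
    if (!identical(rownames(w), labels)) {
      stop("node labels do not match the expected vocabulary")
    }
  } else if (nrow(w) == 90L && is.null(rownames(w))) {
    dimnames(w) <- list(aal90_labels(), aal90_labels())
  }
  validate_connectome(w)
  w
}

#' Write a connectivity matrix as labeled CSV
#'
#' @param w Connectome matrix.
#' @param path Output path.
#' @export
write_connectome <- function(w, path) {
  w <- validate_connectome(w)
  df <- data.frame(node = rownames(w), w, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort table
#'
#' CSV with required columns `subject_id`, `group`, `age`, `sex`,
#' `apoe4`.  Group labels are validated against CN / sMCI / cMCI / AD;
#' duplicate subject ids and missing values are errors.
#'
#' @param path File path.
#' @return Cohort data frame with `group` as a factor.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "group", "age", "sex", "apoe4")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("cohort file missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$subject_id)) {
    stop("duplicate subject_id: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "))
  }
  bad <- setdiff(unique(df$group), GROUP_LEVELS)
  if (length(bad)) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(GROUP_LEVELS, collapse = ", "))
  }
  if (anyNA(df[req])) stop("cohort table contains missing values")
  df$group <- droplevels(factor(df$group, levels = GROUP_LEVELS))
  df
}

#' Write a cohort table as CSV
#'
#' @param cohort Cohort data frame.
#' @param path Output path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a whole cohort of connectomes to a directory
#'
#' One labeled CSV matrix per subject plus `cohort.csv`.
#'
#' @param cc A `"connectome_cohort"`.
#' @param dir Output directory (created if needed).
#' @export
write_cohort_dir <- function(cc, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(cc$cohort, file.path(dir, "cohort.csv"))
  mdir <- file.path(dir, "matrices")
  dir.create(mdir, showWarnings = FALSE)
  for (id in names(cc$connectomes)) {
    write_connectome(cc$connectomes[[id]], file.path(mdir, paste0(id, ".csv")))
  }
  invisible(dir)
}

#' Read a cohort of connectomes from a directory
#'
#' Inverse of [write_cohort_dir()].
#'
#' @param dir Directory containing `cohort.csv` and `matrices/`.
#' @return A `"connectome_cohort"`.
#' @export
read_cohort_dir <- function(dir) {
  cohort <- read_cohort(file.path(dir, "cohort.csv"))
  mats <- lapply(cohort$subject_id, function(id) {
    read_connectome(file.path(dir, "matrices", paste0(id, ".csv")))
  })
  names(mats) <- cohort$subject_id
  connectome_cohort(cohort, mats)
}

# Write a result data frame as TSV (tab-separated, no quoting).
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
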