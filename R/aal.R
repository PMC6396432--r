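#' Node labels of the 90-region AAL parcellation
#'
#' Returns the abbreviations of the 90 non-cerebellar regions of the
#' Automated Anatomical Labeling (AAL) atlas in canonical atlas order
#' (odd indices left hemisphere, even indices right).  This is the fixed
#' node vocabulary used throughout the pipeline; all connectivity
#' matrices are expected to carry these labels (or a user-supplied
#' vocabulary of matching length for non-standard parcellations).
#'
#' @return Character vector of length 90.
#' @examples
#' head(aal90_labels())
#' @export
aal90_labels <- function() {
  path <- system.file("extdata", "aal90_labels.txt", package = "mdmrnet",
                      mustWork = TRUE)
  readLines(path)
}

#' Default node labels for an n-node network
#'
#' AAL-90 abbreviations when `n == 90`, otherwise generic `"R001"`-style
#' labels, so reduced-size simulated networks carry a consistent
#' vocabulary.
#'
#' @param n Number of nodes.
#' @return Character vector of length `n`.
#' @export
node_labels <- function(n) {
  if (n == 90L) aal90_labels() else sprintf("R%03d", seq_len(n))
}

#' Analyzed sample size after screening exclusions
#'
#' Cohort screening bookkeeping: the number of subjects remaining after
#' successive exclusion steps (e.g. non-monotone diagnoses, missing
#' final diagnosis, imaging artifacts) are removed from an initial
#' search result.
#'
#' @param initial Initial subject count (positive integer).
#' @param exclusions Integer vector of subjects removed at each step.
#' @return Integer, the analyzed sample size.
#' @examples
#' screened_sample_size(243, c(29, 38, 15))
#' @export
screened_sample_size <- function(initial, exclusions) {
  stopifnot(length(initial) == 1L, initial >= 0, all(exclusions >= 0))
  out <- initial - sum(exclusions)
  if (out < 0) stop("exclusions exceed the initial sample size")
  as.integer(out)
}
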