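# Construction and manipulation of weighted structural connectivity
# matrices: edge weighting from streamline summaries, density
# thresholding, and extraction of per-region connectivity vectors.

#' Validate a connectivity matrix
#'
#' A connectome is a square, symmetric, nonnegative, finite numeric
#' matrix with a zero diagonal, optionally carrying node labels as
#' dimnames.
#'
#' @param w Numeric matrix.
#' @param tol Tolerance for the symmetry check.
#' @return `w`, invisibly, with dimnames filled in from [node_labels()]
#'   if absent.
#' @export
validate_connectome <- function(w, tol = 1e-8) {
  if (!is.matrix(w) || !is.numeric(w)) stop("connectome must be a numeric matrix")
  n <- nrow(w)
  if (n == 0L) stop("connectome matrix is empty")
  if (ncol(w) != n) stop("connectome must be square, got ", n, " x ", ncol(w))
  if (any(!is.finite(w))) stop("connectome contains non-finite weights")
  neg <- which(w < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative weight at [%d, %d]", neg[1, 1], neg[1, 2]))
  }
  if (max(abs(w - t(w))) > tol) stop("connectome is not symmetric within tolerance ", tol)
  if (any(abs(diag(w)) > tol)) stop("connectome diagonal must be zero")
  if (is.null(dimnames(w))) {
    dimnames(w) <- list(node_labels(n), node_labels(n))
  }
  invisible(w)
}

#' Edge weight from a streamline summary
#'
#' Connection-density edge weight between two parcellation nodes: the
#' number of streamlines per unit end-node surface, each streamline
#' down-weighted by its length,
#' \deqn{w_{ij} = \frac{2}{S_i + S_j} \sum_f \frac{1}{l_f},}
#' where \eqn{S_i, S_j} are the node surface areas and \eqn{l_f} the
#' streamline lengths.  Long spurious streamlines therefore contribute
#' little, and the weight reads as a connection probability density
#' rather than a fiber count.
#'
#' @param streamline_lengths Numeric vector of streamline lengths for
#'   one node pair (possibly empty; all entries must be positive).
#' @param surface_i,surface_j Positive node surface areas.
#' @return Nonnegative scalar weight; 0 when no streamlines connect the
#'   pair.
#' @examples
#' compute_edge_weight(c(2, 4), 10, 10)  # 0.075
#' @export
compute_edge_weight <- function(streamline_lengths, surface_i, surface_j) {
  if (!is.numeric(surface_i) || !is.numeric(surface_j) ||
      surface_i <= 0 || surface_j <= 0) {
    stop("node surface areas must be positive")
  }
  if (length(streamline_lengths) == 0L) return(0)
  if (any(!is.finite(streamline_lengths)) || any(streamline_lengths <= 0)) {
    stop("streamline lengths must be positive and finite")
  }
  as.numeric(2 / (surface_i + surface_j) * sum(1 / streamline_lengths))
}

#' Apply a density threshold to a connectome
#'
#' Retains the strongest edges of the network: the `floor(density * P)`
#' largest upper-triangle weights (with `P = n(n-1)/2` possible edges)
#' are kept and all other weights are set to zero.  Values tied with the
#' cut-off weight are all kept, so the realized density can slightly
#' exceed the target; when that happens the result carries a
#' `"tie_at_threshold"` attribute.  The percentile is taken over all `P`
#' possible edges, zeros included, matching the usual connectomics
#' reading of "density"; set `nonzero_only = TRUE` to rank only the
#' structurally present edges instead.
#'
#' @param w Connectome matrix (see [validate_connectome()]).
#' @param density Fraction of edges to retain, in (0, 1]. Default 0.05,
#'   i.e. the strongest 5 percent (95th percentile) of edge weights.
#' @param nonzero_only Rank only nonzero edges when computing the
#'   cut-off.
#' @return Thresholded connectome of the same shape and dimnames.
#' @export
apply_density_threshold <- function(w, density = 0.05, nonzero_only = FALSE) {
  w <- validate_connectome(w)
  if (!is.numeric(density) || length(density) != 1L || density <= 0 || density > 1) {
    stop("density must be a fraction in (0, 1]")
  }
  n <- nrow(w)
  ut <- upper.tri(w)
  vals <- w[ut]
  pool <- if (nonzero_only) vals[vals > 0] else vals
  keep_n <- floor(density * length(pool))
  if (keep_n >= length(vals[vals > 0])) {
    return(w)  # nothing to remove (includes density = 1)
  }
  if (keep_n == 0L) {
    out <- w
    out[] <- 0
    return(out)
  }
  cut <- sort(pool, decreasing = TRUE)[keep_n]
  out <- w
  out[out < cut] <- 0
  kept <- sum(out[ut] > 0)
  if (kept > keep_n) attr(out, "tie_at_threshold") <- TRUE
  out
}

#' Connectivity vector of a seed region
#'
#' The row of the (typically thresholded) connectivity matrix for one
#' seed region with the diagonal self-entry removed: the weights linking
#' the seed to each of the remaining `n - 1` regions, in fixed node
#' order.  These vectors are the multivariate response profiles compared
#' across subjects by MDMR.
#'
#' @param w Connectome matrix.
#' @param seed_region Node index or label.
#' @return Named numeric vector of length `n - 1`.
#' @export
connectivity_vector <- function(w, seed_region) {
  w <- validate_connectome(w)
  i <- resolve_node(w, seed_region)
  w[i, -i]
}

#' Vectorize the upper triangle of a connectome
#'
#' Flattens the `n(n-1)/2` unique edge weights into a feature vector in
#' fixed lexicographic `(i, j)`, `i < j` order, as used for whole-brain
#' classification (4005 features for the 90-node AAL network).
#'
#' @param w Connectome matrix.
#' @return Named numeric vector of length `n(n-1)/2`; names are
#'   `"<label_i>--<label_j>"`.
#' @export
vectorize_upper_triangle <- function(w) {
  w <- validate_connectome(w)
  pairs <- upper_triangle_pairs(nrow(w))
  out <- w[cbind(pairs[, 1], pairs[, 2])]
  lab <- rownames(w)
  names(out) <- paste0(lab[pairs[, 1]], "--", lab[pairs[, 2]])
  out
}

#' Upper-triangle index pairs in canonical order
#'
#' @param n Number of nodes.
#' @return Integer matrix with columns `i`, `j` (`i < j`), rows ordered
#'   lexicographically: (1,2), (1,3), ..., (n-1,n).
#' @export
upper_triangle_pairs <- function(n) {
  stopifnot(n >= 2)
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  cbind(i = i, j = j)
}

# Resolve a node given as index or label to an integer index.
resolve_node <- function(w, node) {
  if (is.character(node)) {
    i <- match(node, rownames(w))
    if (is.na(i)) stop("unknown node label: ", node)
    return(i)
  }
  i <- as.integer(node)
  if (is.na(i) || i < 1L || i > nrow(w)) {
    stop("node index out of range: ", node)
  }
  i
}
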