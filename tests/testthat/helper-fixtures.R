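# Shared fixtures: all built in code at test time.

# Random valid connectome with distinct weights.
random_connectome <- function(n, seed = 1, density = 1) {
  set.seed(seed)
  w <- matrix(0, n, n)
  P <- n * (n - 1) / 2
  vals <- stats::runif(P)
  if (density < 1) vals[stats::runif(P) > density] <- 0
  w[upper.tri(w)] <- vals
  w <- w + t(w)
  dimnames(w) <- list(node_labels(n), node_labels(n))
  w
}

# Random symmetric distance matrix with entries in [0, 2].
random_distance_matrix <- function(n, seed = 1) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * 8), n)
  as.matrix(stats::dist(X)) / max(stats::dist(X)) * 2
}

# Small scaled cohort used across tests (fast defaults).
small_cohort <- function(seed = 1, effect = 0, n_nodes = 16,
                         groups = c(CN = 10, AD = 10), seeds = integer(0),
                         density = 0.25) {
  sp <- synthetic_spec(
    n_nodes = n_nodes, group_sizes = groups, planted_seeds = seeds,
    effect_size = effect, base_density = density, edge_sdlog = 0.5,
    rng_seed = seed
  )
  generate_cohort(sp)
}

# Brute-force O(n^2) pairwise AUC oracle.
auc_oracle <- function(scores, is_pos) {
  pos <- scores[is_pos]
  neg <- scores[!is_pos]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Benjamini-Hochberg step-up oracle, written from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- prev
  }
  q
}
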