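# Shortest-path machinery shared by the metric suite. All-pairs distances
# are computed with a vectorized Floyd-Warshall sweep, which is exact for
# the non-negative edge lengths used here and fast enough at parcellation
# scale (a few hundred nodes).

# lengths: n x n matrix of direct edge lengths, Inf where no edge, 0 diag.
all_pairs_distances <- function(lengths) {
  d <- lengths
  n <- nrow(d)
  diag(d) <- 0
  for (k in seq_len(n)) {
    via <- outer(d[, k], d[k, ], "+")
    smaller <- via < d
    if (any(smaller)) d[smaller] <- via[smaller]
  }
  d
}

# Direct edge lengths for the binary pattern: 1 per hop.
binary_lengths <- function(w) {
  l <- matrix(Inf, nrow(w), ncol(w))
  l[w > 0] <- 1
  diag(l) <- 0
  l
}

# Direct edge lengths for the weighted case: reciprocal weight, so strong
# connections are short. Weights are expected max-normalized to [0, 1].
inverse_weight_lengths <- function(w) {
  l <- matrix(Inf, nrow(w), ncol(w))
  nz <- w > 0
  l[nz] <- 1 / w[nz]
  diag(l) <- 0
  l
}

# Mean shortest-path distance over reachable ordered off-diagonal pairs,
# plus the count of unreachable ordered pairs.
char_path_length <- function(dist) {
  off <- dist[row(dist) != col(dist)]
  reach <- is.finite(off)
  if (!any(reach)) {
    stop_cw("network has no connected pair; path length undefined. ",
            "Check thresholding/selection did not empty the matrix.",
            class = "cw_domain_error")
  }
  list(L = mean(off[reach]), unreachable = sum(!reach))
}

# Mean inverse shortest-path distance over all ordered off-diagonal pairs;
# unreachable pairs contribute 0.
global_efficiency_from <- function(dist) {
  off <- dist[row(dist) != col(dist)]
  inv <- ifelse(is.finite(off) & off > 0, 1 / off, 0)
  mean(inv)
}
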