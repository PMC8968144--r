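# Shared fixtures and independent oracles. Oracles are deliberately naive
# (double/triple loops, exhaustive enumeration, or igraph) and never call
# the code paths they check.

with_seed_helper <- function(seed, expr) withr::with_seed(seed, expr)

mk_atlas <- function(n, groups = NULL, attributes = NULL) {
  tb <- tibble::tibble(
    parcel = sprintf("P%02d", seq_len(n)),
    legend = sprintf("p%02d", seq_len(n))
  )
  if (!is.null(groups)) tb$group <- groups
  if (!is.null(attributes)) tb <- dplyr::bind_cols(tb, attributes)
  tb
}

# Network whose labels follow atlas order (identity perm).
mk_net <- function(w, groups = NULL) {
  n <- nrow(w)
  atlas <- mk_atlas(n, groups)
  assemble_network(atlas, atlas$parcel, w)
}

rand_net <- function(n, density, seed, groups = NULL) {
  mk_net(generate_random_network(n, density, seed = seed), groups = groups)
}

complete_graph <- function(n, weight = 1) {
  w <- matrix(weight, n, n)
  diag(w) <- 0
  w
}

path_graph <- function(n) {
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    w[i, i + 1] <- 1
    w[i + 1, i] <- 1
  }
  w
}

star_graph <- function(n_leaves) {
  w <- matrix(0, n_leaves + 1, n_leaves + 1)
  w[1, -1] <- 1
  w[-1, 1] <- 1
  w
}

# ---- oracles ---------------------------------------------------------------

# Explicit double-loop permutation: entry (i, j) of the input lands at
# (perm[i], perm[j]) of the output.
oracle_permute <- function(m, perm) {
  n <- nrow(m)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      out[perm[i], perm[j]] <- m[i, j]
    }
  }
  out
}

oracle_gather <- function(m, idx) {
  out <- matrix(0, length(idx), length(idx))
  for (a in seq_along(idx)) {
    for (b in seq_along(idx)) {
      out[a, b] <- m[idx[a], idx[b]]
    }
  }
  out
}

# Brute-force geometric-mean weighted clustering per node over all triples.
oracle_onnela <- function(w) {
  wn <- w / max(w)
  n <- nrow(w)
  k <- rowSums(w > 0)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (k[i] < 2) next
    acc <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j != i && h != i && j != h) {
          acc <- acc + (wn[i, j] * wn[i, h] * wn[j, h])^(1 / 3)
        }
      }
    }
    out[i] <- acc / (k[i] * (k[i] - 1))
  }
  out
}

# Strongest-k edge selection by fully sorting all edges.
oracle_topk <- function(w, k) {
  up <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  wt <- w[up]
  ord <- order(-wt, up[, 1], up[, 2])
  up[ord[seq_len(min(k, length(ord)))], , drop = FALSE]
}

ig_graph <- function(w, weighted = TRUE) {
  igraph::graph_from_adjacency_matrix(
    w, mode = "undirected", weighted = if (weighted) TRUE else NULL,
    diag = FALSE
  )
}

# All set partitions of 1..n (for exhaustive modularity search).
all_partitions <- function(n) {
  if (n == 1) return(list(c(1L)))
  out <- list()
  for (p in all_partitions(n - 1)) {
    m <- max(p)
    for (c in seq_len(m + 1)) {
      out[[length(out) + 1]] <- c(p, c)
    }
  }
  out
}

# All core/periphery assignments of 1..n as logical vectors.
all_assignments <- function(n) {
  g <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  lapply(seq_len(nrow(g)), function(i) as.logical(g[i, ]))
}

expect_symmetric_zero_diag <- function(w) {
  expect_equal(w, t(w))
  expect_true(all(diag(w) == 0))
}
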