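#' Modularity of a partition
#'
#' Weighted Newman modularity with a resolution parameter:
#' `Q = sum_c [ S_in_c / 2m - gamma * (S_tot_c / 2m)^2 ]`, where `S_in_c`
#' is the total weight inside community `c` (both directions), `S_tot_c`
#' the total strength of its nodes, and `2m` the total weight of the graph.
#'
#' @param x A `brain_network` or square weight matrix.
#' @param membership Integer community id per node (display order for a
#'   network).
#' @param gamma Resolution parameter; 1 recovers standard modularity.
#' @return Modularity `Q`.
#' @export
modularity_q <- function(x, membership, gamma = 1) {
  w <- if (inherits(x, "brain_network")) display_matrix(x) else x
  two_m <- sum(w)
  if (two_m == 0) {
    stop_cw("modularity undefined for an edgeless network",
            class = "cw_domain_error")
  }
  k <- rowSums(w)
  q <- 0
  for (c in unique(membership)) {
    idx <- membership == c
    q <- q + sum(w[idx, idx]) / two_m - gamma * (sum(k[idx]) / two_m)^2
  }
  q
}

# One Louvain local-moving sweep over `w` (which may carry aggregated
# self-loops on the diagonal). Nodes are visited in `ord`; each node greedily
# joins the neighbouring community with the largest modularity gain, staying
# put on ties. Returns the (non-compacted) community vector.
louvain_level <- function(w, gamma, ord) {
  n <- nrow(w)
  comm <- seq_len(n)
  k <- rowSums(w)
  two_m <- sum(w)
  tot <- k
  repeat {
    moved <- FALSE
    for (i in ord) {
      ci <- comm[i]
      wi <- w[i, ]
      wi[i] <- 0
      nb <- which(wi > 0)
      if (length(nb) == 0L) next
      links <- rowsum(wi[nb], comm[nb])
      cand <- as.integer(rownames(links))
      tot[ci] <- tot[ci] - k[i]
      gain <- links[, 1] - gamma * k[i] * tot[cand] / two_m
      # staying put must win ties: consider current community first
      stay <- if (ci %in% cand) gain[cand == ci] else
        -gamma * k[i] * tot[ci] / two_m
      best_i <- which.max(gain)
      if (gain[best_i] > stay + 1e-12) {
        best <- cand[best_i]
      } else {
        best <- ci
      }
      tot[best] <- tot[best] + k[i]
      if (best != ci) {
        comm[i] <- best
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  comm
}

#' Community detection by multi-level greedy modularity maximization
#'
#' Louvain-style optimization on the weighted matrix: repeated local-moving
#' sweeps followed by community aggregation until modularity stops
#' improving, restarted `repetitions` times with shuffled node orders; the
#' partition with the best `Q` is kept. Deterministic for a given seed.
#'
#' @param x A `brain_network` or square weight matrix with at least one
#'   edge.
#' @param gamma Resolution parameter (default 1).
#' @param repetitions Number of seeded restarts (default 100).
#' @param seed RNG seed for the restarts (default 1).
#' @return An object of class `cw_communities`: list with `membership`
#'   (integer vector, named by parcel for networks), `q`, `gamma`,
#'   `repetitions`, `seed`, `n_modules`.
#' @export
detect_communities <- function(x, gamma = 1, repetitions = 100, seed = 1) {
  w <- if (inherits(x, "brain_network")) display_matrix(x) else x
  if (sum(w) == 0) {
    stop_cw("community detection needs at least one edge",
            class = "cw_domain_error")
  }
  nm <- rownames(w)
  w <- unname(w)
  best_q <- -Inf
  best_m <- NULL
  with_seed(seed, {
    for (r in seq_len(repetitions)) {
      m <- louvain_run(w, gamma)
      q <- modularity_q(w, m, gamma)
      if (q > best_q + 1e-12) {
        best_q <- q
        best_m <- m
      }
    }
  })
  membership <- match(best_m, unique(best_m))
  if (!is.null(nm)) names(membership) <- nm
  structure(
    list(membership = membership, q = best_q, gamma = gamma,
         repetitions = repetitions, seed = seed,
         n_modules = length(unique(membership))),
    class = "cw_communities"
  )
}

louvain_run <- function(w, gamma) {
  n0 <- nrow(w)
  node_comm <- seq_len(n0)
  cur <- w
  repeat {
    ord <- sample.int(nrow(cur))
    comm <- louvain_level(cur, gamma, ord)
    compact <- match(comm, unique(comm))
    if (max(compact) == nrow(cur)) break  # no merge happened
    node_comm <- compact[node_comm]
    f <- compact
    cur <- rowsum(t(rowsum(cur, f)), f)
    if (nrow(cur) == 1L) break
  }
  node_comm
}

#' @export
print.cw_communities <- function(x, ...) {
  cat(sprintf("<communities> %d modules, Q = %.4f (gamma %.2f, %d restarts)\n",
              x$n_modules, x$q, x$gamma, x$repetitions))
  invisible(x)
}

#' @rdname detect_communities
#' @param ... Unused.
#' @method tidy cw_communities
#' @export
tidy.cw_communities <- function(x, ...) {
  tibble::tibble(
    parcel = names(x$membership) %||% as.character(seq_along(x$membership)),
    module = as.integer(x$membership)
  )
}

#' @rdname detect_communities
#' @method glance cw_communities
#' @export
glance.cw_communities <- function(x, ...) {
  tibble::tibble(q = x$q, n_modules = x$n_modules, gamma = x$gamma,
                 repetitions = x$repetitions, seed = x$seed)
}
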