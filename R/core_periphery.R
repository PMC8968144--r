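# Coreness objective: with B = W - gamma * mean(off-diagonal W) and the
# ideal core-periphery pattern Delta_ij = 1 unless both i and j are
# periphery, q = sum_(i != j) B_ij Delta_ij / sum_(i != j) |B_ij|. A good
# core concentrates above-average weight on core-incident pairs. q is
# defined for every graph (including complete ones, where it is 0 for all
# assignments) and is 0 for the degenerate all-core / all-periphery splits.
coreness_q <- function(w, core, gamma = 1) {
  n <- nrow(w)
  off <- row(w) != col(w)
  b <- w - gamma * mean(w[off])
  scale <- sum(abs(b[off]))
  if (scale == 0) return(0)  # uniform graph: every split equally core-like
  delta <- outer(core, core, "|")
  sum((b * delta)[off]) / scale
}

#' Core-periphery decomposition
#'
#' Splits the nodes into a densely connected core and a sparsely connected
#' periphery by maximizing a density-corrected Borgatti-Everett-style
#' coreness statistic `q` (see Details) with greedy single-node label
#' switching from random initial assignments, restarted `repetitions`
#' times. Isolated nodes are always assigned to the periphery.
#' Deterministic for a given seed.
#'
#' @details The objective compares the observed weights against the ideal
#'   core-periphery pattern after subtracting the mean off-diagonal weight
#'   (scaled by `gamma`), normalized so `q` is comparable across networks:
#'   `q = sum B_ij Delta_ij / sum |B_ij|` with `B = W - gamma * mean(W)` and
#'   `Delta_ij = 1` unless both endpoints are periphery.
#'
#' @param x A `brain_network` or square weight matrix with >= 1 edge.
#' @param gamma Density correction scale (default 1).
#' @param repetitions Random restarts (default 50).
#' @param seed RNG seed (default 1).
#' @return An object of class `cw_core_periphery`: list with `core`
#'   (logical per node, display order), `q`, `repetitions`, `seed`.
#' @export
core_periphery <- function(x, gamma = 1, repetitions = 50, seed = 1) {
  w <- if (inherits(x, "brain_network")) display_matrix(x) else x
  if (sum(w) == 0) {
    stop_cw("core-periphery analysis needs at least one edge",
            class = "cw_domain_error")
  }
  nm <- rownames(w)
  w <- unname(w)
  n <- nrow(w)
  isolated <- rowSums(w > 0) == 0
  best_q <- -Inf
  best_core <- NULL
  with_seed(seed, {
    for (r in seq_len(repetitions)) {
      core <- stats::runif(n) < 0.5
      core[isolated] <- FALSE
      q <- coreness_q(w, core, gamma)
      repeat {
        improved <- FALSE
        for (i in sample.int(n)) {
          if (isolated[i]) next
          cand <- core
          cand[i] <- !cand[i]
          q2 <- coreness_q(w, cand, gamma)
          if (q2 > q + 1e-12) {
            core <- cand
            q <- q2
            improved <- TRUE
          }
        }
        if (!improved) break
      }
      if (q > best_q + 1e-12) {
        best_q <- q
        best_core <- core
      }
    }
  })
  if (!is.null(nm)) names(best_core) <- nm
  structure(
    list(core = best_core, q = best_q, gamma = gamma,
         repetitions = repetitions, seed = seed),
    class = "cw_core_periphery"
  )
}

#' @export
print.cw_core_periphery <- function(x, ...) {
  cat(sprintf("<core-periphery> %d core / %d periphery, q = %.4f\n",
              sum(x$core), sum(!x$core), x$q))
  invisible(x)
}

#' @rdname core_periphery
#' @param ... Unused.
#' @method tidy cw_core_periphery
#' @export
tidy.cw_core_periphery <- function(x, ...) {
  tibble::tibble(
    parcel = names(x$core) %||% as.character(seq_along(x$core)),
    role = ifelse(x$core, "core", "periphery")
  )
}

#' @rdname core_periphery
#' @method glance cw_core_periphery
#' @export
glance.cw_core_periphery <- function(x, ...) {
  tibble::tibble(q = x$q, n_core = sum(x$core), n_periphery = sum(!x$core),
                 repetitions = x$repetitions, seed = x$seed)
}

#' Rich-club coefficient curve
#'
#' For each degree level `k`, the rich-club coefficient is the edge density
#' among the nodes of binary degree greater than `k`:
#' `phi(k) = 2 E_k / (N_k (N_k - 1))`. Levels where fewer than two nodes
#' survive are reported `NA` (undefined).
#'
#' @param x A `brain_network` or square weight matrix.
#' @return A tibble with columns `k`, `n_nodes`, `n_edges`, `phi`, for
#'   `k = 1 .. max degree`.
#' @export
rich_club <- function(x) {
  w <- if (inherits(x, "brain_network")) display_matrix(x) else x
  a <- w > 0
  deg <- rowSums(a)
  kmax <- max(deg)
  if (kmax < 1) {
    stop_cw("rich club undefined for an edgeless network",
            class = "cw_domain_error")
  }
  purrr::map_dfr(seq_len(kmax), function(k) {
    keep <- deg > k
    nk <- sum(keep)
    ek <- sum(a[keep, keep]) / 2
    tibble::tibble(
      k = k, n_nodes = nk, n_edges = ek,
      phi = if (nk >= 2) 2 * ek / (nk * (nk - 1)) else NA_real_
    )
  })
}
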