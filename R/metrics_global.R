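# Degree-preserving rewiring (double-edge swaps) of a binary pattern.
# `swaps_per_edge * E` swap attempts; a swap (a,b),(c,d) -> (a,d),(c,b) is
# applied only if it creates no self-loop or duplicate edge.
rewire_degree_preserving <- function(a, swaps_per_edge = 10) {
  n <- nrow(a)
  edges <- which(upper.tri(a) & a > 0, arr.ind = TRUE)
  ne <- nrow(edges)
  if (ne < 2) return(a)
  attempts <- ceiling(swaps_per_edge * ne)
  for (t in seq_len(attempts)) {
    pick <- sample.int(ne, 2)
    e1 <- edges[pick[1], ]
    e2 <- edges[pick[2], ]
    a1 <- e1[1]; b1 <- e1[2]; c1 <- e2[1]; d1 <- e2[2]
    if (stats::runif(1) < 0.5) { tmp <- c1; c1 <- d1; d1 <- tmp }
    if (a1 == d1 || c1 == b1 || a1 == c1 || b1 == d1) next
    if (a[a1, d1] > 0 || a[c1, b1] > 0) next
    a[a1, b1] <- 0; a[b1, a1] <- 0
    a[c1, d1] <- 0; a[d1, c1] <- 0
    a[a1, d1] <- 1; a[d1, a1] <- 1
    a[c1, b1] <- 1; a[b1, c1] <- 1
    edges[pick[1], ] <- c(min(a1, d1), max(a1, d1))
    edges[pick[2], ] <- c(min(c1, b1), max(c1, b1))
  }
  a
}

# Small-worldness sigma = (C / C_rand) / (L / L_rand), with C and L the
# mean binary clustering and binary characteristic path length, and the
# null values averaged over degree-preserving rewired graphs.
small_worldness <- function(a, nulls = 10, swaps_per_edge = 10, seed = 1) {
  k <- rowSums(a)
  denom <- k * (k - 1)
  cl <- function(m) {
    tri <- diag(m %*% m %*% m)
    mean(ifelse(denom > 0, tri / pmax(denom, 1), 0))
  }
  cpl <- function(m) char_path_length(all_pairs_distances(binary_lengths(m)))$L
  c_obs <- cl(a)
  l_obs <- cpl(a)
  c_rand <- numeric(nulls)
  l_rand <- numeric(nulls)
  with_seed(seed, {
    for (r in seq_len(nulls)) {
      ar <- rewire_degree_preserving(a, swaps_per_edge)
      kr <- rowSums(ar)
      dr <- kr * (kr - 1)
      tri <- diag(ar %*% ar %*% ar)
      c_rand[r] <- mean(ifelse(dr > 0, tri / pmax(dr, 1), 0))
      l_rand[r] <- cpl(ar)
    }
  })
  (c_obs / mean(c_rand)) / (l_obs / mean(l_rand))
}

#' Whole-network (global) graph indices
#'
#' Computes the global index report for a network: average binary degree
#' and average strength; mean binary and weighted clustering coefficients;
#' binary and weighted characteristic path length (mean shortest-path
#' distance over reachable ordered pairs; hop counts for the binary case,
#' reciprocal max-normalized weights for the weighted case); binary and
#' weighted global efficiency (mean inverse distance over all ordered
#' pairs, unreachable pairs contributing 0); small-worldness against
#' degree-preserving rewired nulls; modularity `Q` from
#' [detect_communities()]; coreness statistic `q` from [core_periphery()];
#' and density in percent.
#'
#' @param net A `brain_network` with at least one connected pair.
#' @param nulls Number of rewired null graphs for small-worldness.
#' @param louvain_reps Restarts for community detection.
#' @param cp_reps Restarts for core-periphery switching.
#' @param gamma Resolution for community detection.
#' @param seed RNG seed governing nulls and restarts.
#' @param drop_low_degree Passed to [local_metrics()].
#' @return An object of class `cw_global_metrics`: list with `values`
#'   (named numeric of the 12 indices), `n`, `seed`, `unreachable_pairs`
#'   (binary/weighted counts), and the full `communities` and
#'   `core_periphery` results. Use [tidy()] / [glance()] for tibble views.
#' @export
global_metrics <- function(net, nulls = 10, louvain_reps = 100, cp_reps = 50,
                           gamma = 1, seed = 1, drop_low_degree = FALSE) {
  stopifnot(inherits(net, "brain_network"))
  w <- display_matrix(net)
  n <- nrow(w)
  a <- (w > 0) * 1
  if (sum(a) == 0) {
    stop_cw("network has no edges; global indices undefined. ",
            "Check thresholding/selection did not empty the matrix.",
            class = "cw_domain_error")
  }
  wn <- w / max(w)
  loc <- local_metrics(net, drop_low_degree = drop_low_degree)

  d_bin <- all_pairs_distances(binary_lengths(a))
  d_wei <- all_pairs_distances(inverse_weight_lengths(wn))
  lb <- char_path_length(d_bin)
  lw <- char_path_length(d_wei)

  comm <- detect_communities(w, gamma = gamma, repetitions = louvain_reps,
                             seed = seed)
  cp <- core_periphery(w, repetitions = cp_reps, seed = seed)

  values <- c(
    average_degree = mean(loc$degree),
    average_strength_w = mean(loc$strength),
    clustering_coef = mean(loc$clustering, na.rm = TRUE),
    clustering_coef_w = mean(loc$clustering_w, na.rm = TRUE),
    char_path_length = lb$L,
    char_path_length_w = lw$L,
    global_efficiency = global_efficiency_from(d_bin),
    global_efficiency_w = global_efficiency_from(d_wei),
    small_worldness = small_worldness(a, nulls = nulls, seed = seed),
    modularity = comm$q,
    coreness = cp$q,
    density = network_density(w)
  )
  structure(
    list(values = values, n = n, seed = seed, nulls = nulls,
         unreachable_pairs = c(binary = lb$unreachable,
                               weighted = lw$unreachable),
         communities = comm, core_periphery = cp, local = loc),
    class = "cw_global_metrics"
  )
}

#' @export
print.cw_global_metrics <- function(x, ...) {
  cat(sprintf("<global_metrics> %d parcels (seed %s)\n", x$n, x$seed))
  v <- x$values
  for (i in seq_along(v)) {
    cat(sprintf("  %-22s %s\n", names(v)[i], format(v[i], digits = 6)))
  }
  if (any(x$unreachable_pairs > 0)) {
    cat(sprintf("  (%d binary / %d weighted ordered pairs unreachable)\n",
                x$unreachable_pairs[["binary"]],
                x$unreachable_pairs[["weighted"]]))
  }
  invisible(x)
}

#' @rdname global_metrics
#' @param x A `cw_global_metrics` object.
#' @param ... Unused.
#' @method tidy cw_global_metrics
#' @export
tidy.cw_global_metrics <- function(x, ...) {
  tibble::tibble(index = names(x$values), value = unname(x$values))
}

#' @rdname global_metrics
#' @method glance cw_global_metrics
#' @export
glance.cw_global_metrics <- function(x, ...) {
  out <- tibble::as_tibble(as.list(x$values))
  dplyr::mutate(out, n = x$n, seed = x$seed,
                unreachable_binary = x$unreachable_pairs[["binary"]],
                unreachable_weighted = x$unreachable_pairs[["weighted"]])
}
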