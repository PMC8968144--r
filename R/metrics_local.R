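#' Per-parcel (local) graph indices
#'
#' Computes the local index table for a network: binary degree, weighted
#' degree (strength), binary and weighted clustering coefficients, and
#' binary and weighted local efficiency, one row per parcel in atlas
#' display order.
#'
#' Binary indices are computed on the nonzero pattern. Weighted clustering
#' uses the geometric-mean (cube root) form on internally max-normalized
#' weights: `C_i = sum_(j,h) (w_ij w_ih w_jh)^(1/3) / (k_i (k_i - 1))`.
#' Local efficiency of a node is the global efficiency of the subgraph
#' induced by its neighbours (hop distances for the binary case, reciprocal
#' normalized weights for the weighted case). Strength is reported on the
#' weights as given. Nodes with degree < 2 take clustering and local
#' efficiency 0; set `drop_low_degree = TRUE` to mark them `NA` instead so
#' they drop out of downstream means.
#'
#' @param net A `brain_network` (at least 3 nodes).
#' @param drop_low_degree Mark degree-<2 nodes `NA` instead of 0.
#' @return A tibble with columns `parcel`, `group` (if present), `degree`,
#'   `strength`, `clustering`, `clustering_w`, `efficiency_local`,
#'   `efficiency_local_w`, in display order.
#' @export
local_metrics <- function(net, drop_low_degree = FALSE) {
  stopifnot(inherits(net, "brain_network"))
  w <- unname(display_matrix(net))
  n <- nrow(w)
  if (n < 3L) {
    stop_cw("local indices need at least 3 nodes",
            class = "cw_domain_error")
  }
  a <- (w > 0) * 1
  k <- rowSums(a)
  strength <- rowSums(w)
  wn <- if (max(w) > 0) w / max(w) else w

  # binary clustering: closed triangles over possible triangles
  tri_b <- diag(a %*% a %*% a)
  # weighted clustering, geometric-mean form on normalized weights
  w13 <- wn^(1 / 3)
  tri_w <- diag(w13 %*% w13 %*% w13)
  denom <- k * (k - 1)
  cl_b <- ifelse(denom > 0, tri_b / denom, 0)
  cl_w <- ifelse(denom > 0, tri_w / denom, 0)

  eff_b <- numeric(n)
  eff_w <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] > 0)
    if (length(nb) < 2L) next
    sub_b <- a[nb, nb, drop = FALSE]
    sub_w <- wn[nb, nb, drop = FALSE]
    eff_b[i] <- global_efficiency_from(all_pairs_distances(binary_lengths(sub_b)))
    eff_w[i] <- global_efficiency_from(all_pairs_distances(inverse_weight_lengths(sub_w)))
  }

  if (drop_low_degree) {
    low <- k < 2
    cl_b[low] <- NA_real_
    cl_w[low] <- NA_real_
    eff_b[low] <- NA_real_
    eff_w[low] <- NA_real_
  }

  out <- tibble::tibble(
    parcel = net$atlas$parcel,
    degree = as.integer(k),
    strength = strength,
    clustering = cl_b,
    clustering_w = cl_w,
    efficiency_local = eff_b,
    efficiency_local_w = eff_w
  )
  if ("group" %in% names(net$atlas)) {
    out <- dplyr::mutate(out, group = net$atlas$group, .after = "parcel")
  }
  out
}
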