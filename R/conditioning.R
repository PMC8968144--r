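#' Network density in percent
#'
#' Density is the percentage of the `N(N-1)/2` possible undirected edges
#' that carry a nonzero weight.
#'
#' @param x A `brain_network` or square weight matrix.
#' @return Density in percent (0-100).
#' @export
#' @examples
#' network_density(matrix(c(0, 1, 1, 0), 2, 2)) # 100
network_density <- function(x) {
  w <- weights_of(x)
  n <- nrow(w)
  if (n < 2L) {
    stop_cw("density undefined for fewer than 2 nodes",
            class = "cw_domain_error")
  }
  100 * sum(w[upper.tri(w)] > 0) / (n * (n - 1) / 2)
}

#' Density-based thresholding
#'
#' Retains the `k` strongest edges, `k = round(target_density * N(N-1)/2)`
#' (half away from zero), equivalent to iteratively raising an absolute
#' threshold from zero until the requested density is best approximated.
#' Ties at the cutoff weight are broken deterministically by lexicographic
#' `(i, j)` upper-triangle order. If the matrix is already at or below the
#' target density it is returned unchanged with a warning.
#'
#' @param x A `brain_network` or square weight matrix.
#' @param target_density Fraction in (0, 1] of possible edges to keep.
#' @param binarize If `TRUE`, surviving weights are set to 1.
#' @return Same type as `x`, thresholded.
#' @export
apply_density_threshold <- function(x, target_density, binarize = FALSE) {
  if (!is.numeric(target_density) || length(target_density) != 1L ||
      target_density <= 0 || target_density > 1) {
    stop_cw("target_density must be in (0, 1]", class = "cw_domain_error")
  }
  w <- weights_of(x)
  n <- nrow(w)
  e_max <- n * (n - 1) / 2
  k <- round_half_up(target_density * e_max)
  up <- upper_pairs(n)
  wt <- w[up]
  nz <- which(wt > 0)
  if (k >= length(nz)) {
    if (k > length(nz)) {
      warning(sprintf(
        "target density %.4f exceeds current density %.4f; matrix unchanged",
        target_density, length(nz) / e_max), call. = FALSE)
    }
    out <- w
    if (binarize) out[out > 0] <- 1
  } else {
    ord <- nz[order(-wt[nz], up[nz, 1], up[nz, 2])]
    keep <- ord[seq_len(k)]
    out <- matrix(0, n, n, dimnames = dimnames(w))
    ik <- up[keep, , drop = FALSE]
    val <- if (binarize) 1 else wt[keep]
    out[ik] <- val
    out[ik[, c(2, 1), drop = FALSE]] <- val
  }
  if (inherits(x, "brain_network")) set_weights(x, out) else out
}

#' Normalize weights by the maximum edge value
#'
#' Divides every weight by the maximum weight so that values range in
#' `[0, 1]`; weight ratios are preserved and the operation is idempotent.
#'
#' @param x A `brain_network` or square weight matrix with at least one
#'   nonzero weight.
#' @return Same type as `x`, max-normalized.
#' @export
normalize_by_max <- function(x) {
  w <- weights_of(x)
  mx <- max(w)
  if (mx == 0) {
    stop_cw("cannot max-normalize an all-zero matrix",
            class = "cw_domain_error")
  }
  out <- w / mx
  if (inherits(x, "brain_network")) set_weights(x, out) else out
}

#' Normalize weights by summed parcel volumes
#'
#' Divides each weight (e.g. a reconstructed-fiber count) by the sum of the
#' volumes of the two parcels it connects, accounting for parcel-size
#' differences: `out[i, j] = in[i, j] / (vol[i] + vol[j])`.
#'
#' @param x A `brain_network` or square weight matrix.
#' @param volumes Numeric vector of strictly positive per-parcel volumes,
#'   length `N`, in the matrix row order of `x` (matrix order for a
#'   `brain_network`). May be named; names are not used for alignment.
#' @return Same type as `x`, volume-normalized.
#' @export
normalize_by_parcel_volumes <- function(x, volumes) {
  w <- weights_of(x)
  n <- nrow(w)
  if (length(volumes) != n) {
    stop_cw("volumes must have length ", n, class = "cw_dimension_error")
  }
  bad <- which(!is.finite(volumes) | volumes <= 0)
  if (length(bad) > 0) {
    nm <- if (!is.null(names(volumes))) names(volumes)[bad[1]] else bad[1]
    stop_cw("non-positive volume for parcel ", nm, class = "cw_domain_error")
  }
  denom <- outer(volumes, volumes, "+")
  out <- w / denom
  diag(out) <- 0
  if (inherits(x, "brain_network")) set_weights(x, out) else out
}

#' Group consensus matrix from per-subject matrices
#'
#' Builds a single group-representative matrix from a stack of same-order
#' subject matrices: an edge is retained only if it is present (nonzero) in
#' at least `ceiling(presence * S)` of the `S` subjects; the retained
#' weight is the mean of that edge's weight across subjects. By default the
#' mean runs over all `S` subjects (subjects lacking the edge contribute
#' zero); `mean_over = "present"` averages over the subjects that have the
#' edge only. Non-retained edges are set to zero.
#'
#' @param matrices List of square weight matrices (or `brain_network`s),
#'   all of the same dimension and node order.
#' @param presence Minimum fraction of subjects that must share an edge,
#'   in `[0, 1]`. Default 0.53.
#' @param mean_over `"all"` or `"present"`.
#' @return A consensus weight matrix.
#' @export
build_group_matrix <- function(matrices, presence = 0.53,
                               mean_over = c("all", "present")) {
  mean_over <- match.arg(mean_over)
  if (!is.list(matrices) || length(matrices) < 2L) {
    stop_cw("need at least 2 subject matrices", class = "cw_dimension_error")
  }
  if (!is.numeric(presence) || presence < 0 || presence > 1) {
    stop_cw("presence must be in [0, 1]", class = "cw_domain_error")
  }
  ws <- lapply(matrices, weights_of)
  n <- nrow(ws[[1]])
  ok <- vapply(ws, function(m) nrow(m) == n && ncol(m) == n, logical(1))
  if (!all(ok)) {
    stop_cw("subject matrices differ in dimension",
            class = "cw_dimension_error")
  }
  s <- length(ws)
  need <- ceiling(presence * s)
  count <- Reduce(`+`, lapply(ws, function(m) (m > 0) * 1))
  total <- Reduce(`+`, ws)
  keep <- count >= need
  avg <- if (mean_over == "all") {
    total / s
  } else {
    out <- total
    nz <- count > 0
    out[nz] <- total[nz] / count[nz]
    out
  }
  res <- avg * keep
  diag(res) <- 0
  res
}
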