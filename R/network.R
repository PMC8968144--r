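#' Assemble a brain network from atlas, labels and matrix
#'
#' Aligns the three inputs into one analyzable object. The label vector
#' gives the row/column order of the matrix; the atlas gives the display
#' order used for every rendering and report. The permutation between the
#' two is computed here once and the matrix itself is left untouched; it is
#' reordered only when a display-order view is requested. This is what lets
#' one atlas serve many label/matrix pairs while keeping the circular
#' layout stable.
#'
#' @param atlas Atlas tibble from [load_atlas()] (or equivalent data frame
#'   with `parcel` and `legend` columns). May contain parcels absent from
#'   `labels`; those are dropped from the assembled network.
#' @param labels Character vector of parcel names in matrix order, from
#'   [load_labels()].
#' @param weights Square symmetric weight matrix, from [load_matrix()] or
#'   [validate_matrix()].
#' @return An object of class `brain_network`: a list with `atlas` (rows in
#'   display order), `labels` (matrix order), `weights` (matrix order) and
#'   `perm` (`perm[i]` = display position of matrix index `i`).
#' @export
#' @examples
#' atlas <- tibble::tibble(parcel = c("A", "B", "C"),
#'                         legend = c("a", "b", "c"))
#' m <- matrix(c(0, 1, 0, 1, 0, 2, 0, 2, 0), 3, 3)
#' net <- assemble_network(atlas, c("C", "A", "B"), m)
#' net$perm
assemble_network <- function(atlas, labels, weights) {
  validate_atlas(atlas)
  weights <- validate_matrix(weights)
  if (length(labels) != nrow(weights)) {
    stop_cw("label count (", length(labels),
            ") does not match matrix dimension (", nrow(weights), ")",
            class = "cw_dimension_error")
  }
  unknown <- setdiff(labels, atlas$parcel)
  if (length(unknown) > 0) {
    stop_cw("label(s) not found in atlas: ",
            paste(unknown, collapse = ", "), class = "cw_lookup_error")
  }
  dup <- unique(labels[duplicated(labels)])
  if (length(dup) > 0) {
    stop_cw("duplicate label(s): ", paste(dup, collapse = ", "),
            class = "cw_format_error")
  }
  display_names <- atlas$parcel[atlas$parcel %in% labels]
  perm <- match(labels, display_names)
  structure(
    list(
      atlas = tibble::as_tibble(atlas[match(display_names, atlas$parcel), ]),
      labels = labels,
      weights = weights,
      perm = perm
    ),
    class = "brain_network"
  )
}

#' @export
print.brain_network <- function(x, ...) {
  n <- n_nodes(x)
  e <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("<brain_network> %d parcels, %d edges (density %.2f%%)\n",
              n, e, network_density(x)))
  if ("group" %in% names(x$atlas)) {
    cat("  groups:", paste(unique(x$atlas$group), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of nodes of a network or matrix
#' @param x A `brain_network` or square matrix.
#' @return Integer node count.
#' @export
n_nodes <- function(x) {
  if (inherits(x, "brain_network")) nrow(x$weights) else nrow(x)
}

# Extract the weight matrix from either representation.
weights_of <- function(x) {
  if (inherits(x, "brain_network")) x$weights else x
}

#' Weight matrix in atlas display order
#'
#' Returns the connectivity matrix with rows/columns permuted so that index
#' `k` corresponds to the `k`-th atlas (display) parcel. Dimnames are set
#' to the parcel names.
#'
#' @param net A `brain_network`.
#' @return A square matrix in display order.
#' @export
display_matrix <- function(net) {
  stopifnot(inherits(net, "brain_network"))
  ord <- order(net$perm)
  m <- net$weights[ord, ord, drop = FALSE]
  dimnames(m) <- list(net$atlas$parcel, net$atlas$parcel)
  m
}

#' Edge list of a network as a tibble
#'
#' One row per nonzero upper-triangle edge, endpoints named by parcel, in
#' display order.
#'
#' @param x A `brain_network`.
#' @param ... Unused.
#' @return A tibble with columns `from`, `to`, `weight`.
#' @method tidy brain_network
#' @export
tidy.brain_network <- function(x, ...) {
  m <- display_matrix(x)
  idx <- which(upper.tri(m) & m > 0, arr.ind = TRUE)
  tibble::tibble(
    from = x$atlas$parcel[idx[, 1]],
    to = x$atlas$parcel[idx[, 2]],
    weight = m[idx]
  ) |>
    dplyr::arrange(match(.data$from, x$atlas$parcel),
                   match(.data$to, x$atlas$parcel))
}

# Rebuild a network around a new display-order matrix (identity perm).
network_from_display <- function(atlas, disp_weights) {
  structure(
    list(
      atlas = tibble::as_tibble(atlas),
      labels = atlas$parcel,
      weights = unname(disp_weights),
      perm = seq_len(nrow(disp_weights))
    ),
    class = "brain_network"
  )
}

# Replace the weights of a network (matrix order), revalidating.
set_weights <- function(net, weights) {
  net$weights <- validate_matrix(weights)
  net
}
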