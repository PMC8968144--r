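#' Expand selection tokens into a parcel set
#'
#' A token selects parcels by exact parcel name, by group tag, or by the
#' value of any attribute column, with that precedence: a token equal to a
#' parcel name always selects that single parcel; a token that is not a
#' parcel name but matches both a group tag and an attribute value is
#' ambiguous and raises an error; a token matching nothing raises an error
#' naming it. The result is the de-duplicated union over all tokens, with
#' provenance recording which token matched each parcel and how.
#'
#' @param atlas Atlas tibble (display order).
#' @param tokens Character vector of parcel names, group tags and/or
#'   attribute tags.
#' @return A tibble with columns `index` (display index), `parcel`,
#'   `token`, `matched_by` (`"parcel"`, `"group"` or attribute column
#'   name), one row per selected parcel (first matching token kept).
#' @export
expand_selection <- function(atlas, tokens) {
  validate_atlas(atlas)
  if (length(tokens) == 0L) {
    stop_cw("no selection tokens given", class = "cw_selection_error")
  }
  attr_cols <- atlas_attribute_columns(atlas)
  hits <- purrr::map(tokens, function(tk) {
    if (tk %in% atlas$parcel) {
      return(tibble::tibble(index = which(atlas$parcel == tk),
                            token = tk, matched_by = "parcel"))
    }
    in_group <- "group" %in% names(atlas) &&
      tk %in% stats::na.omit(atlas$group)
    attr_match <- attr_cols[vapply(attr_cols, function(cl) {
      tk %in% stats::na.omit(atlas[[cl]])
    }, logical(1))]
    n_cat <- sum(in_group) + length(attr_match)
    if (n_cat == 0L) {
      stop_cw("selection token matches nothing: '", tk, "'",
              class = "cw_selection_error")
    }
    if (n_cat > 1L) {
      stop_cw("ambiguous selection token '", tk,
              "': matches more than one of group/attribute tags",
              class = "cw_selection_error")
    }
    if (in_group) {
      tibble::tibble(index = which(!is.na(atlas$group) & atlas$group == tk),
                     token = tk, matched_by = "group")
    } else {
      cl <- attr_match[[1]]
      tibble::tibble(index = which(!is.na(atlas[[cl]]) & atlas[[cl]] == tk),
                     token = tk, matched_by = cl)
    }
  })
  dplyr::bind_rows(hits) |>
    dplyr::distinct(.data$index, .keep_all = TRUE) |>
    dplyr::arrange(.data$index) |>
    dplyr::mutate(parcel = atlas$parcel[.data$index], .after = "index")
}

# Resolve a selection argument (token character vector, expand_selection
# tibble, or display-index integer vector) to sorted display indices.
resolve_indices <- function(net, sel, arg = "selection") {
  n <- n_nodes(net)
  if (is.data.frame(sel) && "index" %in% names(sel)) {
    idx <- sel$index
  } else if (is.character(sel)) {
    idx <- expand_selection(net$atlas, sel)$index
  } else if (is.numeric(sel)) {
    idx <- as.integer(sel)
  } else {
    stop_cw(arg, " must be parcel tokens, indices or an expand_selection() ",
            "result", class = "cw_selection_error")
  }
  idx <- sort(unique(idx))
  if (length(idx) == 0L) {
    stop_cw(arg, " is empty", class = "cw_selection_error")
  }
  if (any(idx < 1L | idx > n)) {
    stop_cw(arg, " contains out-of-range indices", class = "cw_selection_error")
  }
  idx
}

#' Seed-target exploration mask
#'
#' Implements exploration from a selected subset: only edges joining a seed
#' parcel to a target parcel are kept; every other edge is suppressed. The
#' node set is unchanged, so all parcels remain on the connectogram ring.
#' Seeds may also appear among the targets, in which case seed-seed edges
#' are kept too. Seed/target are conventional names; the mask is symmetric.
#'
#' @param net A `brain_network`.
#' @param seeds,targets Selections (tokens, display indices, or
#'   [expand_selection()] results); both must be nonempty.
#' @return An `N x N` logical edge mask in display order (symmetric, `FALSE`
#'   diagonal): `TRUE` where the edge is kept.
#' @export
explore_from_seeds <- function(net, seeds, targets) {
  stopifnot(inherits(net, "brain_network"))
  s <- resolve_indices(net, seeds, "seeds")
  t <- resolve_indices(net, targets, "targets")
  n <- n_nodes(net)
  in_s <- seq_len(n) %in% s
  in_t <- seq_len(n) %in% t
  keep <- outer(in_s, in_t, "&") | outer(in_t, in_s, "&")
  diag(keep) <- FALSE
  keep
}

#' Extract an induced subgraph as a new network
#'
#' Returns a new, physically smaller network over the selected parcels
#' only, retaining the original weights between every pair of selected
#' parcels. Atlas display order is preserved among the survivors.
#'
#' @param net A `brain_network`.
#' @param nodes Selection of at least 2 parcels.
#' @return A new `brain_network` over the selected parcels.
#' @export
extract_subgraph <- function(net, nodes) {
  stopifnot(inherits(net, "brain_network"))
  idx <- resolve_indices(net, nodes, "nodes")
  if (length(idx) < 2L) {
    stop_cw("subgraph extraction needs at least 2 parcels",
            class = "cw_selection_error")
  }
  m <- display_matrix(net)
  network_from_display(net$atlas[idx, ], m[idx, idx, drop = FALSE])
}

#' Mask suppressing within-group edges
#'
#' Keeps only edges whose endpoints carry different tags in the given
#' grouping column, hiding short-range (within-lobe) connections so that
#' long-range structure stands out. Parcels with a missing tag are treated
#' as singleton groups (their edges are kept).
#'
#' @param net A `brain_network`.
#' @param grouping Name of the atlas column holding the grouping tag.
#' @return Logical edge mask in display order.
#' @export
omit_within_group_edges <- function(net, grouping = "group") {
  stopifnot(inherits(net, "brain_network"))
  if (!grouping %in% names(net$atlas)) {
    stop_cw("atlas has no '", grouping, "' column",
            class = "cw_configuration_error")
  }
  g <- net$atlas[[grouping]]
  g[is.na(g)] <- paste0(".na", seq_len(sum(is.na(g))))
  keep <- outer(g, g, "!=")
  diag(keep) <- FALSE
  keep
}

#' Apply an edge mask to a network
#'
#' Returns a new network (in display order) whose weights are zeroed
#' wherever the mask is `FALSE`. The original network is never modified, so
#' masked views can always be compared against the complete matrix.
#'
#' @param net A `brain_network`.
#' @param mask Logical `N x N` mask in display order (e.g. from
#'   [explore_from_seeds()] or [omit_within_group_edges()]).
#' @return A new `brain_network`.
#' @export
apply_mask <- function(net, mask) {
  stopifnot(inherits(net, "brain_network"))
  n <- n_nodes(net)
  if (!is.matrix(mask) || !is.logical(mask) ||
      nrow(mask) != n || ncol(mask) != n) {
    stop_cw("mask must be an N x N logical matrix",
            class = "cw_dimension_error")
  }
  m <- display_matrix(net)
  m[!mask] <- 0
  network_from_display(net$atlas, m)
}
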