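#' Build the drawable geometry of a connectogram
#'
#' Computes everything needed to draw a circular connectogram: node
#' positions on the ring (atlas order, first parcel on top, clockwise),
#' contiguous group segments, and one Poincare-disk arc per kept edge.
#' Returns data, not a drawing; [autoplot.cw_connectogram()] turns it into
#' a ggplot and [render_connectogram()] writes files.
#'
#' @param net A `brain_network`.
#' @param mask Optional logical edge mask in display order (e.g. from
#'   [explore_from_seeds()] or [omit_within_group_edges()]); only masked-in
#'   edges are drawn. Node ring is unaffected.
#' @param style Optional list of style settings: `edge_color_mode`
#'   (`"uniform"` or `"weight"`), `node_color_metric` (name of a
#'   [local_metrics()] column, or `NULL`), `hide_labels` (parcel names
#'   whose labels are hidden), `suppress_nodes` (parcel names whose
#'   incident edges are removed), `group_colors` (named vector).
#' @return An object of class `cw_connectogram`: list with tibbles `nodes`,
#'   `arcs` (ascending weight, so strong edges draw on top), `groups`
#'   (contiguous segment spans) and the resolved `style`.
#' @export
build_connectogram <- function(net, mask = NULL, style = list()) {
  stopifnot(inherits(net, "brain_network"))
  style <- utils::modifyList(
    list(edge_color_mode = "uniform", node_color_metric = NULL,
         hide_labels = character(), suppress_nodes = character(),
         group_colors = NULL),
    style
  )
  w <- display_matrix(net)
  n <- nrow(w)
  keep <- w > 0
  if (!is.null(mask)) {
    if (!is.matrix(mask) || nrow(mask) != n || ncol(mask) != n) {
      stop_cw("mask must be an N x N logical matrix in display order",
              class = "cw_dimension_error")
    }
    keep <- keep & mask
  }
  if (length(style$suppress_nodes) > 0) {
    sup <- match(style$suppress_nodes, net$atlas$parcel)
    if (anyNA(sup)) {
      stop_cw("unknown parcel in suppress_nodes: ",
              paste(style$suppress_nodes[is.na(sup)], collapse = ", "),
              class = "cw_configuration_error")
    }
    keep[sup, ] <- FALSE
    keep[, sup] <- FALSE
  }
  diag(keep) <- FALSE

  layout <- circular_layout(net$atlas)
  nodes <- dplyr::mutate(layout,
                         label_visible = !.data$parcel %in% style$hide_labels)
  if (!is.null(style$node_color_metric)) {
    loc <- local_metrics(net)
    if (!style$node_color_metric %in% names(loc)) {
      stop_cw("unknown node color metric '", style$node_color_metric, "'",
              class = "cw_configuration_error")
    }
    nodes$node_value <- loc[[style$node_color_metric]]
  }

  idx <- which(upper.tri(keep) & keep, arr.ind = TRUE)
  arcs <- if (nrow(idx) == 0L) {
    tibble::tibble(i = integer(), j = integer(), weight = numeric(),
                   kind = character(), ux = numeric(), uy = numeric(),
                   vx = numeric(), vy = numeric(), cx = numeric(),
                   cy = numeric(), r = numeric(), a0 = numeric(),
                   a1 = numeric())
  } else {
    geo <- purrr::map2_dfr(idx[, 1], idx[, 2], function(i, j) {
      poincare_arc(c(nodes$x[i], nodes$y[i]), c(nodes$x[j], nodes$y[j]))
    })
    dplyr::bind_cols(
      tibble::tibble(i = idx[, 1], j = idx[, 2], weight = w[idx]),
      geo
    ) |>
      dplyr::arrange(.data$weight)
  }

  groups <- if ("group" %in% names(nodes)) {
    runs <- rle(nodes$group)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    tibble::tibble(
      group = runs$values,
      from_angle = nodes$angle[starts],
      to_angle = nodes$angle[ends]
    )
  } else {
    tibble::tibble(group = character(), from_angle = numeric(),
                   to_angle = numeric())
  }

  structure(
    list(nodes = nodes, arcs = arcs, groups = groups, style = style,
         n_edges = nrow(arcs)),
    class = "cw_connectogram"
  )
}

#' @export
print.cw_connectogram <- function(x, ...) {
  cat(sprintf("<connectogram> %d nodes on ring, %d arcs, %d group segments\n",
              nrow(x$nodes), nrow(x$arcs), nrow(x$groups)))
  invisible(x)
}

#' Draw a connectogram
#'
#' @param object A `cw_connectogram` from [build_connectogram()].
#' @param arc_resolution Points interpolated per arc.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cw_connectogram
#' @export
autoplot.cw_connectogram <- function(object, arc_resolution = 64, ...) {
  nodes <- object$nodes
  arcs <- object$arcs
  style <- object$style

  p <- ggplot2::ggplot() +
    ggplot2::coord_equal(xlim = c(-1.55, 1.55), ylim = c(-1.55, 1.55)) +
    ggplot2::theme_void()

  if (nrow(arcs) > 0) {
    pts <- arcs |>
      dplyr::mutate(edge = dplyr::row_number()) |>
      dplyr::rowwise() |>
      dplyr::group_split() |>
      purrr::map_dfr(function(row) {
        dplyr::bind_cols(arc_points(row, n = arc_resolution),
                         edge = row$edge, weight = row$weight)
      })
    if (identical(style$edge_color_mode, "weight")) {
      p <- p + ggplot2::geom_path(
        data = pts,
        ggplot2::aes(x = .data$x, y = .data$y, group = .data$edge,
                     colour = .data$weight),
        linewidth = 0.3, alpha = 0.8
      ) +
        ggplot2::scale_colour_viridis_c(name = "weight", limits = c(0, NA))
    } else {
      p <- p + ggplot2::geom_path(
        data = pts,
        ggplot2::aes(x = .data$x, y = .data$y, group = .data$edge),
        colour = "grey35", linewidth = 0.3, alpha = 0.8
      )
    }
  }

  if (nrow(object$groups) > 0) {
    seg_pts <- object$groups |>
      dplyr::mutate(seg = dplyr::row_number()) |>
      purrr::pmap_dfr(function(group, from_angle, to_angle, seg) {
        pad <- 0.45 * 2 * pi / max(nrow(nodes), 1)
        t <- seq(from_angle + pad, to_angle - pad, length.out = 24)
        tibble::tibble(x = 1.06 * cos(t), y = 1.06 * sin(t),
                       group = group, seg = seg)
      })
    lab_pts <- object$groups |>
      dplyr::mutate(mid = (.data$from_angle + .data$to_angle) / 2,
                    x = 1.32 * cos(.data$mid), y = 1.32 * sin(.data$mid))
    p <- p +
      ggplot2::geom_path(
        data = seg_pts,
        ggplot2::aes(x = .data$x, y = .data$y, group = .data$seg,
                     colour = NULL),
        colour = "grey60", linewidth = 2, lineend = "butt",
        show.legend = FALSE
      ) +
      ggplot2::geom_text(
        data = lab_pts,
        ggplot2::aes(x = .data$x, y = .data$y, label = .data$group),
        size = 3
      )
  }

  if (!is.null(style$node_color_metric)) {
    p <- p + ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$node_value),
      shape = 21, size = 1.6, stroke = 0.2
    ) +
      ggplot2::scale_fill_viridis_c(name = style$node_color_metric,
                                    option = "plasma")
  } else if ("group" %in% names(nodes)) {
    p <- p + ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y),
      colour = "grey20", size = 1.2
    )
  } else {
    p <- p + ggplot2::geom_point(
      data = nodes, ggplot2::aes(x = .data$x, y = .data$y),
      colour = "grey20", size = 1.2
    )
  }

  labs <- dplyr::filter(nodes, .data$label_visible)
  if (nrow(labs) > 0) {
    labs <- dplyr::mutate(
      labs,
      deg = .data$angle * 180 / pi,
      flip = cos(.data$angle) < 0,
      text_angle = ifelse(.data$flip, .data$deg + 180, .data$deg),
      hj = ifelse(.data$flip, 1, 0)
    )
    p <- p + ggplot2::geom_text(
      data = labs,
      ggplot2::aes(x = 1.10 * .data$x, y = 1.10 * .data$y,
                   label = .data$legend, angle = .data$text_angle,
                   hjust = .data$hj),
      size = 1.8
    )
  }
  p
}

#' @export
plot.cw_connectogram <- function(x, ...) {
  print(autoplot(x, ...))
  invisible(x)
}

#' Render a connectogram to SVG and/or PNG
#'
#' Builds the connectogram for a network (plus optional mask and style)
#' and writes figure files to `out_dir`. SVG is drawn with the cairo SVG
#' device (deterministic output for fixed inputs); PNG is rasterized at
#' `dpi`.
#'
#' @inheritParams build_connectogram
#' @param out_dir Output directory (created if needed).
#' @param name File base name.
#' @param formats Any of `"svg"`, `"png"`.
#' @param width,height Figure size in inches.
#' @param dpi PNG resolution.
#' @return Invisibly, the `cw_connectogram` with a `files` attribute of
#'   written paths.
#' @export
render_connectogram <- function(net, mask = NULL, style = list(),
                                out_dir = ".", name = "connectogram",
                                formats = c("svg", "png"),
                                width = 8, height = 8, dpi = 150) {
  cg <- build_connectogram(net, mask = mask, style = style)
  p <- autoplot(cg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  if ("svg" %in% formats) {
    f <- file.path(out_dir, paste0(name, ".svg"))
    grDevices::svg(f, width = width, height = height)
    print(p)
    grDevices::dev.off()
    normalize_svg_ids(f)
    files <- c(files, f)
  }
  if ("png" %in% formats) {
    f <- file.path(out_dir, paste0(name, ".png"))
    grDevices::png(f, width = width * dpi, height = height * dpi, res = dpi)
    print(p)
    grDevices::dev.off()
    files <- c(files, f)
  }
  attr(cg, "files") <- files
  invisible(cg)
}

# The cairo SVG device numbers embedded raster sources with a
# session-global counter; rewrite those ids in order of appearance so
# identical figures are byte-identical regardless of device history.
normalize_svg_ids <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  ids <- unique(unlist(regmatches(txt, gregexpr("source-[0-9]+", txt))))
  for (i in seq_along(ids)) {
    txt <- gsub(paste0("\\b", ids[i], "\\b"), paste0("raster-", i), txt)
  }
  writeLines(txt, path)
  invisible(path)
}
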