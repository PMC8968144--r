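#' Dot plot of a local index with top/bottom highlighting
#'
#' Plots one local index per parcel in atlas display order, over vertical
#' background stripes marking the parcel groups (homologous left/right
#' groups share a color: a trailing `-L`/`-R` or `_L`/`_R` hemisphere
#' suffix in the group tag is stripped before coloring). The top and
#' bottom `fraction` of parcels by index value are drawn red and yellow
#' respectively, all others blue, following [highlight_classes()].
#'
#' @param table Local index tibble from [local_metrics()] (display order).
#' @param metric Column of `table` to plot (e.g. `"degree"`).
#' @param fraction Highlight fraction per class (default 0.10).
#' @return A ggplot object.
#' @export
plot_local_index <- function(table, metric = "degree", fraction = 0.10) {
  if (!metric %in% names(table)) {
    stop_cw("metric '", metric, "' not found in local index table",
            class = "cw_configuration_error")
  }
  vals <- table[[metric]]
  n <- nrow(table)
  df <- tibble::tibble(
    pos = seq_len(n),
    parcel = table$parcel,
    value = vals,
    class = highlight_classes(vals, fraction)
  )
  p <- ggplot2::ggplot()
  if ("group" %in% names(table)) {
    runs <- rle(table$group)
    ends <- cumsum(runs$lengths)
    stripes <- tibble::tibble(
      group = runs$values,
      xmin = ends - runs$lengths + 0.5,
      xmax = ends + 0.5,
      base = stringr::str_remove(runs$values, "[-_ ]?[LR]$")
    )
    p <- p + ggplot2::geom_rect(
      data = stripes,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf, fill = .data$base),
      alpha = 0.25, show.legend = TRUE
    ) +
      ggplot2::labs(fill = "group")
  }
  p +
    ggplot2::geom_point(
      data = df,
      ggplot2::aes(x = .data$pos, y = .data$value, colour = .data$class),
      size = 1.4
    ) +
    ggplot2::scale_colour_manual(
      values = c(top = "red", mid = "blue", bottom = "gold2"),
      name = NULL,
      labels = c(top = sprintf("top %.0f%%", 100 * fraction),
                 mid = "mid", bottom = sprintf("least %.0f%%", 100 * fraction))
    ) +
    ggplot2::labs(x = "parcel (atlas order)", y = metric) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid.minor = ggplot2::element_blank())
}

#' Render a local-index plot to SVG and/or PNG
#'
#' @inheritParams plot_local_index
#' @inheritParams render_connectogram
#' @return Invisibly, the written file paths.
#' @export
render_local_index_plot <- function(table, metric = "degree",
                                    fraction = 0.10, out_dir = ".",
                                    name = paste0("local_", metric),
                                    formats = c("svg", "png"),
                                    width = 10, height = 4, dpi = 150) {
  p <- plot_local_index(table, metric, fraction)
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
  invisible(files)
}
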