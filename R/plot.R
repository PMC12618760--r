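#' Corn-plot style rendering of per-position values
#'
#' Draws one panel per stage, with a tile at every position's layout cell
#' colored by the supplied value — the grid depiction used for embryo
#' sections (rows follow the section index along the proximal-to-distal
#' axis, so higher section indices are drawn lower; set `flip = TRUE` to
#' invert). `mode = "pdi"` uses a diverging palette centered at 0 with
#' symmetric limits at the largest absolute value, so sign is always
#' legible; `mode = "pcc"` uses a sequential palette over the observed
#' range. Undefined (`NA`) cells are grey with a cross mark. Domain codes
#' are printed on the tiles.
#'
#' @param values Named numeric vector keyed by position id (e.g. one row of
#'   a `pcc_map` or one column of a `pdi_map`).
#' @param atlas The `atlas_ref` supplying layout coordinates.
#' @param mode `"pcc"` or `"pdi"` — selects the palette.
#' @param title Optional plot title.
#' @param flip If `TRUE`, draw low section indices at the bottom.
#' @return A ggplot object.
#' @export
plot_spatial_map <- function(values, atlas, mode = c("pcc", "pdi"),
                             title = NULL, flip = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(atlas, "atlas_ref"))
  if (is.null(names(values))) {
    stop_stpheno("`values` must be named by position id.", "stpheno_bad_input")
  }
  pos <- atlas$positions
  missing_layout <- pos$position_id[is.na(pos$layout_row) | is.na(pos$layout_col)]
  if (length(missing_layout)) {
    stop_stpheno(paste0("positions without layout coordinates: ",
                        id_list(missing_layout)),
                 "stpheno_bad_input")
  }
  df <- pos |>
    mutate(value = unname(values[.data$position_id]))

  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$layout_col, y = .data$layout_row)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$value), color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$domain_code), size = 2.6) +
    ggplot2::geom_point(data = df[is.na(df$value), , drop = FALSE],
                        shape = 4, size = 3, color = "grey40") +
    ggplot2::facet_wrap(~stage) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid = ggplot2::element_blank(),
                   axis.title = ggplot2::element_blank(),
                   axis.text = ggplot2::element_blank())
  p <- if (flip) p + ggplot2::scale_y_continuous() else p + ggplot2::scale_y_reverse()

  if (mode == "pdi") {
    lim <- max(abs(df$value), na.rm = TRUE)
    if (!is.finite(lim) || lim == 0) lim <- 1
    p <- p + ggplot2::scale_fill_gradient2(
      low = "#2166AC", mid = "#F7F7F7", high = "#B2182B",
      limits = c(-lim, lim), na.value = "grey85", name = "PDI")
  } else {
    p <- p + ggplot2::scale_fill_gradient(
      low = "#F7FBFF", high = "#08306B", na.value = "grey85", name = "PCC")
  }
  if (!is.null(title)) p <- p + ggplot2::ggtitle(title)
  p
}

#' Render a spatial map to an SVG file
#'
#' Thin file-writing wrapper around [plot_spatial_map()]; output is
#' deterministic for fixed input.
#'
#' @inheritParams plot_spatial_map
#' @param out_path Output path (`.svg`).
#' @param width,height Device size in inches.
#' @return `out_path`, invisibly.
#' @export
render_spatial_map <- function(values, atlas, out_path, mode = c("pcc", "pdi"),
                               title = NULL, flip = FALSE,
                               width = 6, height = 4) {
  p <- plot_spatial_map(values, atlas, mode = mode, title = title, flip = flip)
  grDevices::svg(out_path, width = width, height = height)
  ok <- FALSE
  tryCatch({ print(p); ok <- TRUE }, finally = grDevices::dev.off())
  if (ok) normalize_svg_ids(out_path)
  invisible(out_path)
}

# the svg device numbers embedded raster sources with a session-global
# counter; renumber them per file so identical input gives identical bytes
normalize_svg_ids <- function(path) {
  txt <- readLines(path, warn = FALSE)
  ids <- unique(unlist(regmatches(txt, gregexpr("source-[0-9]+", txt))))
  stable <- setNames(sprintf("src-%d", seq_along(ids)), ids)
  # replace longest ids first so source-2 never clips source-22
  for (id in ids[order(-nchar(ids))]) {
    txt <- gsub(id, stable[[id]], txt, fixed = TRUE)
  }
  writeLines(txt, path)
  invisible(path)
}

#' Autoplot a correlation map
#'
#' @param object A `pcc_map`.
#' @param atlas The `atlas_ref` the map was computed against.
#' @param sample Sample id to draw (default: the first).
#' @param ... Passed to [plot_spatial_map()].
#' @return A ggplot object.
#' @method autoplot pcc_map
#' @export
autoplot.pcc_map <- function(object, atlas, sample = rownames(object$pcc)[1], ...) {
  plot_spatial_map(object$pcc[sample, ], atlas, mode = "pcc",
                   title = sample, ...)
}

#' Autoplot a PDI map
#'
#' @param object A `pdi_map`.
#' @param atlas The `atlas_ref` the underlying correlations were computed
#'   against.
#' @param comparison Comparison label to draw (default: the first).
#' @param ... Passed to [plot_spatial_map()].
#' @return A ggplot object.
#' @method autoplot pdi_map
#' @export
autoplot.pdi_map <- function(object, atlas, comparison = colnames(object$pdi)[1], ...) {
  plot_spatial_map(object$pdi[, comparison], atlas, mode = "pdi",
                   title = comparison, ...)
}
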