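#' Rendering configuration
#'
#' @param palette ordered vector of colors, one per marker group (cycled when
#'   there are more groups than colors). Default is the Okabe-Ito
#'   colorblind-safe qualitative scheme; `brick_palette("classic")` gives the
#'   orange/pink/purple/yellow preset familiar from published Brick plots.
#' @param label_mode `"all"` (label every rendered brick), `"none"`, or
#'   `"min_side"` (label only bricks at least `min_label_side` of the layout
#'   span wide, keeping small-brick labels from cluttering the figure).
#' @param output_format `"svg"` (canonical; structurally testable) or
#'   `"png"` (rasterized at `dpi`).
#' @param figure_size width/height in inches (plots are square: equal aspect
#'   keeps areas visually truthful).
#' @param show_variance_axes annotate axes as "PC1 (p% variance)" etc.
#' @param font_size label font size in points.
#' @param min_label_side fraction of the layout span for `"min_side"` mode.
#' @param dpi raster resolution for PNG output.
#' @return A list of class `render_config`.
#' @export
render_config <- function(palette = brick_palette("okabe-ito"),
                          label_mode = c("all", "none", "min_side"),
                          output_format = c("svg", "png"),
                          figure_size = 6,
                          show_variance_axes = TRUE,
                          font_size = 9,
                          min_label_side = 0.02,
                          dpi = 150) {
  label_mode <- match.arg(label_mode)
  output_format <- match.arg(output_format)
  if (length(palette) < 1) bp_stop("palette must be non-empty", "bp_value_error")
  ok <- vapply(palette, function(cl)
    tryCatch({ grDevices::col2rgb(cl); TRUE }, error = function(e) FALSE),
    logical(1))
  if (!all(ok))
    bp_stop(sprintf("invalid color specification: %s",
                    paste(palette[!ok], collapse = ", ")), "bp_value_error")
  structure(list(palette = unname(palette), label_mode = label_mode,
                 output_format = output_format, figure_size = figure_size,
                 show_variance_axes = isTRUE(show_variance_axes),
                 font_size = font_size, min_label_side = min_label_side,
                 dpi = dpi),
            class = "render_config")
}

#' Named palettes for marker groups
#'
#' @param name `"okabe-ito"` (accessible default) or `"classic"` (the
#'   orange / pink / purple / yellow grouping colors of the original plots).
#' @return Character vector of hex colors.
#' @export
brick_palette <- function(name = c("okabe-ito", "classic")) {
  switch(match.arg(name),
    "okabe-ito" = c("#E69F00", "#56B4E9", "#009E73", "#F0E442",
                    "#0072B2", "#D55E00", "#CC79A7", "#999999"),
    "classic" = c("#F28E2B", "#E868A2", "#8B5FBF", "#EDC948"))
}

## World-to-canvas geometry shared by SVG and PNG backends. Equal aspect:
## one world unit maps to the same number of device units on both axes.
render_geometry <- function(plot, layout, config) {
  mk <- layout$markers
  shown <- plot$bricks[!plot$bricks$zeroed, , drop = FALSE]
  xs <- c(mk$pc1, shown$x - shown$side / 2, shown$x + shown$side / 2)
  ys <- c(mk$pc2, shown$y - shown$side / 2, shown$y + shown$side / 2)
  pad <- 0.06 * max(diff(range(xs)), diff(range(ys)), 1e-9)
  list(xlim = range(xs) + c(-pad, pad), ylim = range(ys) + c(-pad, pad))
}

#' Render a Brick plot to SVG or PNG
#'
#' Draws one square per non-zeroed brick, filled by its marker-group color,
#' with optional marker labels and "PC1 (p% variance)" axis captions. SVG is
#' the canonical format: every brick is one `rect` element of class
#' `"brick"`, so the file is structurally auditable, and the viewBox uses
#' equal aspect so areas are truthful. The plot object is never modified.
#'
#' @param plot a `brick_plot`.
#' @param layout the `marker_layout` the plot was built from.
#' @param config a [render_config()].
#' @param path output file path; the format is taken from `config`.
#' @return `path`, invisibly.
#' @export
render_plot <- function(plot, layout, config = render_config(), path) {
  if (!identical(plot$bricks$marker, layout$markers$name))
    bp_stop("plot and layout marker sets differ", "bp_alignment_error")
  if (!sum(!plot$bricks$zeroed))
    bp_warn(sprintf("cluster '%s' has no bricks above threshold; rendering an empty frame",
                    plot$cluster_id), "bp_empty_plot_warning")
  if (config$output_format == "svg") render_svg(plot, layout, config, path)
  else render_png(plot, layout, config, path)
  invisible(path)
}

render_svg <- function(plot, layout, config, path) {
  geo <- render_geometry(plot, layout, config)
  w_px <- config$figure_size * 96
  world_w <- diff(geo$xlim); world_h <- diff(geo$ylim)
  scale <- w_px / max(world_w, world_h)
  # world -> SVG user units, y flipped (SVG y grows downward)
  tx <- function(x) (x - geo$xlim[1]) * scale
  ty <- function(y) (geo$ylim[2] - y) * scale
  width <- world_w * scale; height <- world_h * scale
  num <- function(z) sprintf("%.4f", z)

  doc <- xml2::xml_new_root(
    "svg", xmlns = "http://www.w3.org/2000/svg", version = "1.1",
    width = num(width), height = num(height),
    viewBox = paste(0, 0, num(width), num(height)))
  xml2::xml_add_child(doc, "rect", class = "frame", x = "0", y = "0",
                      width = num(width), height = num(height),
                      fill = "white", stroke = "#444444")
  title <- xml2::xml_add_child(doc, "text", class = "title",
                               x = num(8), y = num(14),
                               "font-size" = num(config$font_size + 2),
                               "font-family" = "sans-serif")
  xml2::xml_text(title) <- paste0("Cluster ", plot$cluster_id)

  shown <- plot$bricks[!plot$bricks$zeroed, , drop = FALSE]
  span <- max(world_w, world_h)
  if (nrow(shown)) {
    for (i in seq_len(nrow(shown))) {
      b <- shown[i, ]
      fill <- config$palette[((b$group - 1) %% length(config$palette)) + 1]
      xml2::xml_add_child(doc, "rect", class = "brick",
                          id = paste0("brick-", b$marker),
                          x = num(tx(b$x - b$side / 2)),
                          y = num(ty(b$y + b$side / 2)),
                          width = num(b$side * scale),
                          height = num(b$side * scale),
                          fill = fill, "fill-opacity" = "0.9",
                          stroke = "#333333", "stroke-width" = "0.5")
    }
    lab <- switch(config$label_mode,
                  all = seq_len(nrow(shown)),
                  none = integer(0),
                  min_side = which(shown$side >= config$min_label_side * span))
    for (i in lab) {
      b <- shown[i, ]
      # centered under the brick, offset by a fixed fraction of its side
      node <- xml2::xml_add_child(doc, "text", class = "brick-label",
                                  x = num(tx(b$x)),
                                  y = num(ty(b$y - b$side / 2) +
                                          config$font_size + 0.15 * b$side * scale),
                                  "text-anchor" = "middle",
                                  "font-size" = num(config$font_size),
                                  "font-family" = "sans-serif")
      xml2::xml_text(node) <- b$marker
    }
  }
  if (config$show_variance_axes) {
    ax1 <- xml2::xml_add_child(doc, "text", class = "axis-label axis-x",
                               x = num(width / 2), y = num(height - 4),
                               "text-anchor" = "middle",
                               "font-size" = num(config$font_size),
                               "font-family" = "sans-serif")
    xml2::xml_text(ax1) <- sprintf("PC1 (%.1f%% variance)", layout$pc1_var_pct)
    ax2 <- xml2::xml_add_child(doc, "text", class = "axis-label axis-y",
                               x = num(12), y = num(height / 2),
                               "text-anchor" = "middle",
                               "font-size" = num(config$font_size),
                               "font-family" = "sans-serif",
                               transform = sprintf("rotate(-90 %s %s)",
                                                   num(12), num(height / 2)))
    xml2::xml_text(ax2) <- sprintf("PC2 (%.1f%% variance)", layout$pc2_var_pct)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

render_png <- function(plot, layout, config, path) {
  geo <- render_geometry(plot, layout, config)
  grDevices::png(path, width = config$figure_size, height = config$figure_size,
                 units = "in", res = config$dpi)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(3, 3, 2, 1))
  graphics::plot(NA, xlim = geo$xlim, ylim = geo$ylim, asp = 1,
                 xlab = "", ylab = "", axes = FALSE,
                 main = paste0("Cluster ", plot$cluster_id))
  graphics::box()
  if (config$show_variance_axes) {
    graphics::mtext(sprintf("PC1 (%.1f%% variance)", layout$pc1_var_pct),
                    side = 1, line = 1, cex = 0.8)
    graphics::mtext(sprintf("PC2 (%.1f%% variance)", layout$pc2_var_pct),
                    side = 2, line = 1, cex = 0.8)
  }
  shown <- plot$bricks[!plot$bricks$zeroed, , drop = FALSE]
  if (nrow(shown)) {
    fill <- config$palette[((shown$group - 1) %% length(config$palette)) + 1]
    graphics::rect(shown$x - shown$side / 2, shown$y - shown$side / 2,
                   shown$x + shown$side / 2, shown$y + shown$side / 2,
                   col = grDevices::adjustcolor(fill, alpha.f = 0.9),
                   border = "#333333")
    span <- max(diff(geo$xlim), diff(geo$ylim))
    lab <- switch(config$label_mode,
                  all = seq_len(nrow(shown)),
                  none = integer(0),
                  min_side = which(shown$side >= config$min_label_side * span))
    if (length(lab))
      graphics::text(shown$x[lab], shown$y[lab] - shown$side[lab] / 2,
                     labels = shown$marker[lab], pos = 1,
                     cex = config$font_size / 12)
  }
  invisible(path)
}

#' Count brick rectangles in a rendered SVG
#'
#' Structural audit helper: parses the SVG and counts `rect` elements of
#' class `"brick"`. Equals the plot's non-zeroed brick count.
#'
#' @param path an SVG file written by [render_plot()].
#' @return Integer count.
#' @export
count_svg_bricks <- function(path) {
  doc <- xml2::read_xml(path)
  length(xml2::xml_find_all(doc, "//svg:rect[@class='brick']",
                            ns = c(svg = "http://www.w3.org/2000/svg")))
}
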