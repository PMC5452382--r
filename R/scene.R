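# Figure backend. All plots are first assembled into a device-independent
# "scene" (a display list of geometric primitives on a unit canvas, y
# pointing up), then rendered either through base graphics onto the
# pdf()/png()/tiff() devices or serialized directly to SVG. The SVG writer
# keeps labels as literal <text> nodes (so figures remain searchable and
# text-extraction tests are possible) and formats all coordinates with
# fixed precision, making repeated renders byte-identical.

new_scene <- function(width = 7, height = 7, bg = "white") {
  e <- new.env(parent = emptyenv())
  e$width <- width; e$height <- height; e$bg <- bg
  e$prims <- list()
  class(e) <- "ovz_scene"
  e
}

scene_add <- function(scene, prim) {
  scene$prims[[length(scene$prims) + 1L]] <- prim
  invisible(scene)
}

sc_circle <- function(scene, cx, cy, r, fill = NA, stroke = "black",
                      lwd = 1, alpha = 1) {
  scene_add(scene, list(type = "circle", cx = cx, cy = cy, r = r,
                        fill = fill, stroke = stroke, lwd = lwd, alpha = alpha))
}

sc_ellipse <- function(scene, cx, cy, rx, ry, rot = 0, fill = NA,
                       stroke = "black", lwd = 1, alpha = 1) {
  scene_add(scene, list(type = "ellipse", cx = cx, cy = cy, rx = rx, ry = ry,
                        rot = rot, fill = fill, stroke = stroke, lwd = lwd,
                        alpha = alpha))
}

sc_polygon <- function(scene, x, y, fill = NA, stroke = "black", lwd = 1,
                       alpha = 1) {
  scene_add(scene, list(type = "polygon", x = x, y = y, fill = fill,
                        stroke = stroke, lwd = lwd, alpha = alpha))
}

sc_rect <- function(scene, x0, y0, x1, y1, fill = "grey60", stroke = NA,
                    lwd = 1, alpha = 1) {
  scene_add(scene, list(type = "rect", x0 = x0, y0 = y0, x1 = x1, y1 = y1,
                        fill = fill, stroke = stroke, lwd = lwd, alpha = alpha))
}

sc_segments <- function(scene, x0, y0, x1, y1, stroke = "black", lwd = 1) {
  scene_add(scene, list(type = "segments", x0 = x0, y0 = y0, x1 = x1, y1 = y1,
                        stroke = stroke, lwd = lwd))
}

sc_text <- function(scene, x, y, label, size = 11, col = "black",
                    anchor = "middle", angle = 0, bold = FALSE) {
  scene_add(scene, list(type = "text", x = x, y = y, label = as.character(label),
                        size = size, col = col, anchor = anchor, angle = angle,
                        bold = bold))
}

ellipse_xy <- function(cx, cy, rx, ry, rot, n = 240L) {
  th <- seq(0, 2 * pi, length.out = n)
  a <- rot * pi / 180
  x0 <- rx * cos(th); y0 <- ry * sin(th)
  list(x = cx + x0 * cos(a) - y0 * sin(a),
       y = cy + x0 * sin(a) + y0 * cos(a))
}

fill_col <- function(fill, alpha) {
  if (is.na(fill)) NA else grDevices::adjustcolor(fill, alpha.f = alpha)
}

render_scene_device <- function(scene, path, format, dpi = 300) {
  w <- scene$width; h <- scene$height
  switch(format,
    pdf  = grDevices::pdf(path, width = w, height = h, onefile = FALSE),
    png  = grDevices::png(path, width = w, height = h, units = "in",
                          res = dpi, type = "cairo"),
    tiff = grDevices::tiff(path, width = w, height = h, units = "in",
                           res = dpi, type = "cairo", compression = "lzw"),
    stop(sprintf("unsupported device format '%s'", format))
  )
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i", bg = scene$bg)
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, 1), ylim = c(0, 1))
  asp <- h / w  # text size baseline: device pointsize 12
  for (p in scene$prims) {
    switch(p$type,
      circle = {
        xy <- ellipse_xy(p$cx, p$cy, p$r, p$r / asp * asp, 0)
        graphics::polygon(xy$x, xy$y, col = fill_col(p$fill, p$alpha),
                          border = p$stroke, lwd = p$lwd)
      },
      ellipse = {
        xy <- ellipse_xy(p$cx, p$cy, p$rx, p$ry, p$rot)
        graphics::polygon(xy$x, xy$y, col = fill_col(p$fill, p$alpha),
                          border = p$stroke, lwd = p$lwd)
      },
      polygon = graphics::polygon(p$x, p$y, col = fill_col(p$fill, p$alpha),
                                  border = p$stroke, lwd = p$lwd),
      rect = graphics::rect(p$x0, p$y0, p$x1, p$y1,
                            col = fill_col(p$fill, p$alpha),
                            border = p$stroke, lwd = p$lwd),
      segments = graphics::segments(p$x0, p$y0, p$x1, p$y1, col = p$stroke,
                                    lwd = p$lwd),
      text = {
        adj <- switch(p$anchor, middle = 0.5, start = 0, end = 1)
        graphics::text(p$x, p$y, p$label, cex = p$size / 12, col = p$col,
                       adj = c(adj, 0.5), srt = p$angle,
                       font = if (p$bold) 2L else 1L)
      }
    )
  }
  invisible(path)
}

svg_num <- function(x) sprintf("%.2f", x)

svg_esc <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

svg_style <- function(fill, stroke, lwd, alpha) {
  f <- if (is.na(fill)) "fill:none" else
    sprintf("fill:%s;fill-opacity:%.3f", svg_hex(fill), alpha)
  s <- if (is.na(stroke)) "stroke:none" else
    sprintf("stroke:%s;stroke-width:%.2f", svg_hex(stroke), lwd)
  paste(f, s, sep = ";")
}

svg_hex <- function(col) {
  rgb <- grDevices::col2rgb(col)
  sprintf("#%02X%02X%02X", rgb[1L], rgb[2L], rgb[3L])
}

render_scene_svg <- function(scene, path) {
  W <- scene$width * 72; H <- scene$height * 72
  tx <- function(x) x * W
  ty <- function(y) (1 - y) * H
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%s" ',
                   'height="%s" viewBox="0 0 %s %s">'),
            svg_num(W), svg_num(H), svg_num(W), svg_num(H)),
    sprintf('<rect x="0" y="0" width="%s" height="%s" style="fill:%s;stroke:none"/>',
            svg_num(W), svg_num(H), svg_hex(scene$bg))
  )
  for (p in scene$prims) {
    out <- c(out, switch(p$type,
      circle = sprintf('<circle cx="%s" cy="%s" r="%s" style="%s"/>',
                       svg_num(tx(p$cx)), svg_num(ty(p$cy)), svg_num(p$r * W),
                       svg_style(p$fill, p$stroke, p$lwd, p$alpha)),
      ellipse = sprintf(
        '<ellipse cx="0" cy="0" rx="%s" ry="%s" transform="translate(%s %s) rotate(%s)" style="%s"/>',
        svg_num(p$rx * W), svg_num(p$ry * H), svg_num(tx(p$cx)),
        svg_num(ty(p$cy)), svg_num(-p$rot),
        svg_style(p$fill, p$stroke, p$lwd, p$alpha)),
      polygon = sprintf('<polygon points="%s" style="%s"/>',
                        paste(sprintf("%s,%s", svg_num(tx(p$x)),
                                      svg_num(ty(p$y))), collapse = " "),
                        svg_style(p$fill, p$stroke, p$lwd, p$alpha)),
      rect = sprintf('<rect x="%s" y="%s" width="%s" height="%s" style="%s"/>',
                     svg_num(tx(pmin(p$x0, p$x1))), svg_num(ty(pmax(p$y0, p$y1))),
                     svg_num(abs(p$x1 - p$x0) * W), svg_num(abs(p$y1 - p$y0) * H),
                     svg_style(p$fill, p$stroke, p$lwd, p$alpha)),
      segments = sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" style="%s"/>',
                         svg_num(tx(p$x0)), svg_num(ty(p$y0)),
                         svg_num(tx(p$x1)), svg_num(ty(p$y1)),
                         svg_style(NA, p$stroke, p$lwd, 1)),
      text = {
        anchor <- switch(p$anchor, middle = "middle", start = "start",
                         end = "end")
        rot <- if (p$angle != 0)
          sprintf(' transform="rotate(%s %s %s)"', svg_num(-p$angle),
                  svg_num(tx(p$x)), svg_num(ty(p$y))) else ""
        sprintf(paste0('<text x="%s" y="%s" text-anchor="%s" ',
                       'dominant-baseline="middle" font-family="sans-serif" ',
                       'font-size="%s"%s style="fill:%s"%s>%s</text>'),
                svg_num(tx(p$x)), svg_num(ty(p$y)), anchor, svg_num(p$size),
                if (p$bold) ' font-weight="bold"' else "",
                svg_hex(p$col), rot, svg_esc(p$label))
      }
    ))
  }
  out <- c(out, "</svg>")
  con <- file(path, "wb")
  writeLines(out, con, sep = "\n")
  close(con)
  invisible(path)
}

FIG_FORMATS <- c("pdf", "svg", "png", "tiff")

render_scene <- function(scene, path, format, dpi = 300) {
  format <- match.arg(format, FIG_FORMATS)
  if (format == "svg") render_scene_svg(scene, path)
  else render_scene_device(scene, path, format, dpi)
  path
}

#' Figure styling options
#'
#' @param format one of `"pdf"`, `"svg"`, `"png"`, `"tiff"`, or `"all"` to
#'   write every format.
#' @param dpi raster resolution (>= 72).
#' @param colors per-set fill colors; defaults to a colorblind-safe
#'   six-color palette, recycled if fewer than the number of sets.
#' @param fontsize base font size in points.
#' @param title figure title.
#' @param width,height canvas size in inches.
#' @param extra named list of figure-family options (`sort` for UpSet,
#'   `style` for heat maps, `show_empty` for Venn/UpSet).
#' @return list of class `figure_spec`.
#' @export
figure_spec <- function(format = "pdf", dpi = 300, colors = NULL,
                        fontsize = 11, title = "", width = 7, height = 7,
                        extra = list()) {
  if (!identical(format, "all")) format <- match.arg(format, FIG_FORMATS)
  stopifnot(dpi >= 72)
  structure(list(format = format, dpi = dpi,
                 colors = if (is.null(colors)) DEFAULT_PALETTE else colors,
                 fontsize = fontsize, title = title, width = width,
                 height = height, extra = extra),
            class = "figure_spec")
}

# Okabe-Ito derived colorblind-safe palette.
DEFAULT_PALETTE <- c("#0072B2", "#D55E00", "#009E73", "#CC79A7",
                     "#F0E442", "#56B4E9")

spec_colors <- function(spec, n) {
  rep_len(spec$colors, n)
}

# Render one scene under `base` path for each requested format; returns the
# written file paths.
render_formats <- function(scene, base, spec) {
  formats <- if (identical(spec$format, "all")) FIG_FORMATS else spec$format
  vapply(formats, function(f)
    render_scene(scene, paste0(base, ".", f), f, spec$dpi), "")
}
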