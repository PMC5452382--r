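# The three figure families: classical Venn diagrams (2-6 sets), UpSet
# plots, and (clustered) pairwise heat maps. Each function assembles a
# scene and renders it in the requested format(s); layout is fully
# deterministic so repeated renders are byte-identical.

darken <- function(col, f = 0.6) {
  rgb <- grDevices::col2rgb(col) * f
  grDevices::rgb(rgb[1L], rgb[2L], rgb[3L], maxColorValue = 255)
}

#' Draw a classical Venn diagram of a combination table
#'
#' Renders circles (2-3 sets) or fixed ellipse/triangle templates (4-6
#' sets) with every one of the 2^n - 1 category counts placed at a
#' precomputed label anchor; empty categories are printed as 0. More than
#' six sets cannot be drawn as a classical Venn diagram — use
#' [plot_upset()] instead.
#'
#' @param tab a `combination_table` (from [combination_counts()] or
#'   [list_combination_counts()]).
#' @param spec a [figure_spec()].
#' @param path output path without extension.
#' @return Character vector of written file paths.
#' @export
plot_venn <- function(tab, spec = figure_spec(), path = "venn") {
  stopifnot(inherits(tab, "combination_table"))
  n <- length(tab$labels)
  if (n < 2L || n > 6L) {
    stop("Venn diagrams support 2 to 6 sets; use plot_upset() for more")
  }
  counts <- full_counts(tab)
  va <- venn_anchors(n)
  cols <- spec_colors(spec, n)
  sc <- new_scene(spec$width, spec$height)
  for (i in seq_len(n)) {
    s <- va$template$shapes[[i]]
    if (s$kind == "circle") {
      sc_circle(sc, s$cx, s$cy, s$r, fill = cols[i], stroke = darken(cols[i]),
                lwd = 1.4, alpha = 0.35)
    } else if (s$kind == "ellipse") {
      sc_ellipse(sc, s$cx, s$cy, s$rx, s$ry, s$rot, fill = cols[i],
                 stroke = darken(cols[i]), lwd = 1.4, alpha = 0.35)
    } else {
      sc_polygon(sc, s$x, s$y, fill = cols[i], stroke = darken(cols[i]),
                 lwd = 1.4, alpha = 0.25)
    }
  }
  fallback <- character()
  for (mk in seq_len(2^n - 1)) {
    a <- va$anchors[mk, ]
    lab <- format_num(counts[[as.character(mk)]])
    if (is.na(a[1L])) {
      fallback <- c(fallback,
                    sprintf("%s: %s", mask_label(mk, tab$labels), lab))
    } else {
      sc_text(sc, a[1L], a[2L], lab, size = spec$fontsize * (if (n >= 5) 0.8 else 1))
    }
  }
  if (length(fallback) > 0L) {
    for (i in seq_along(fallback)) {
      sc_text(sc, 0.02, 0.05 - 0.03 * (i - 1), fallback[i],
              size = spec$fontsize * 0.7, anchor = "start")
    }
  }
  sl <- venn_setlabel_anchors(n)
  for (i in seq_len(n)) {
    sc_text(sc, sl[i, 1L], sl[i, 2L], tab$labels[i],
            size = spec$fontsize * 1.1, col = darken(cols[i], 0.5),
            bold = TRUE)
  }
  if (nzchar(spec$title)) {
    sc_text(sc, 0.5, 0.97, spec$title, size = spec$fontsize * 1.3,
            bold = TRUE)
  }
  render_formats(sc, path, spec)
}

#' Deterministic ranking of intersection categories for UpSet display
#'
#' @param counts named count vector (names = membership bitmasks).
#' @param labels set labels.
#' @param sort_by `"frequency"` (descending count; ties by ascending degree
#'   then lexicographic combination string) or `"degree"` (ascending
#'   degree; ties by descending count).
#' @return Integer permutation of `counts`.
#' @export
upset_order <- function(counts, labels, sort_by = "frequency") {
  mask <- as.numeric(names(counts))
  deg <- mask_degree(mask)
  combo <- mask_label(mask, labels)
  if (sort_by == "degree") order(deg, -counts, combo, method = "radix")
  else order(-counts, deg, combo, method = "radix")
}

#' Draw an UpSet plot of a combination table
#'
#' Intersection-size bar panel on top, membership dot matrix below, per-set
#' size bars on the left. Combinations are ranked by frequency by default
#' (`spec$extra$sort = "degree"` ranks by degree instead; ties break by
#' count, then lexicographic combination string). Empty combinations are
#' hidden unless `spec$extra$show_empty` is `TRUE`.
#'
#' @inheritParams plot_venn
#' @param set_sizes optional named per-set totals for the left bars;
#'   defaults to each set's total across categories.
#' @return Character vector of written file paths.
#' @export
plot_upset <- function(tab, spec = figure_spec(), path = "upset",
                       set_sizes = NULL) {
  stopifnot(inherits(tab, "combination_table"))
  n <- length(tab$labels)
  sort_by <- spec$extra$sort %||% "frequency"
  show_empty <- isTRUE(spec$extra$show_empty)
  counts <- if (show_empty && n <= 10L) full_counts(tab) else tab$counts
  if (length(counts) == 0L || sum(counts) == 0) {
    stop("combination table has no non-empty categories")
  }
  ord <- upset_order(counts, tab$labels, sort_by)
  counts <- counts[ord]
  mask <- as.numeric(names(counts))
  k <- length(counts)
  if (is.null(set_sizes)) {
    set_sizes <- vapply(seq_len(n), function(i)
      sum(counts[bitwAnd(as.integer(mask), bitwShiftL(1L, i - 1L)) != 0L]), 0)
  }
  cols <- spec_colors(spec, n)
  sc <- new_scene(spec$width, spec$height)

  mat_x0 <- 0.33; mat_x1 <- 0.97
  mat_y0 <- 0.06; mat_y1 <- 0.40
  bar_y0 <- 0.46; bar_y1 <- 0.88
  xs <- mat_x0 + (seq_len(k) - 0.5) / k * (mat_x1 - mat_x0)
  ys <- mat_y1 - (seq_len(n) - 0.5) / n * (mat_y1 - mat_y0)
  colw <- (mat_x1 - mat_x0) / k

  # striped background rows
  for (i in seq_len(n)) {
    if (i %% 2L == 1L) {
      sc_rect(sc, mat_x0, ys[i] - (mat_y1 - mat_y0) / n / 2,
              mat_x1, ys[i] + (mat_y1 - mat_y0) / n / 2, fill = "#F0F0F0")
    }
  }
  # intersection-size bars + counts
  cmax <- max(counts)
  for (j in seq_len(k)) {
    h <- counts[j] / cmax * (bar_y1 - bar_y0)
    sc_rect(sc, xs[j] - colw * 0.32, bar_y0, xs[j] + colw * 0.32, bar_y0 + h,
            fill = "#3B3B3B")
    sc_text(sc, xs[j], bar_y0 + h + 0.018, format_num(counts[j]),
            size = spec$fontsize * 0.75)
  }
  # membership dot matrix
  r <- min(0.012, colw * 0.3, (mat_y1 - mat_y0) / n * 0.32)
  for (j in seq_len(k)) {
    member <- which(bitwAnd(as.integer(mask[j]),
                            bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    for (i in seq_len(n)) {
      sc_circle(sc, xs[j], ys[i], r,
                fill = if (i %in% member) "#3B3B3B" else "#D8D8D8",
                stroke = NA)
    }
    if (length(member) > 1L) {
      sc_segments(sc, xs[j], ys[max(member)], xs[j], ys[min(member)],
                  stroke = "#3B3B3B", lwd = 2)
    }
  }
  # per-set size bars (grow leftward) + labels
  sb_x1 <- 0.20; sb_x0 <- 0.03
  smax <- max(set_sizes, 1)
  for (i in seq_len(n)) {
    w <- set_sizes[i] / smax * (sb_x1 - sb_x0)
    rh <- (mat_y1 - mat_y0) / n * 0.32
    sc_rect(sc, sb_x1 - w, ys[i] - rh, sb_x1, ys[i] + rh, fill = cols[i])
    sc_text(sc, sb_x1 + 0.015, ys[i], tab$labels[i],
            size = spec$fontsize * 0.85, anchor = "start")
  }
  sc_text(sc, (sb_x0 + sb_x1) / 2, mat_y0 - 0.035, "Set size",
          size = spec$fontsize * 0.8)
  sc_text(sc, 0.03, (bar_y0 + bar_y1) / 2, "Intersection size",
          size = spec$fontsize * 0.9, angle = 90)
  if (nzchar(spec$title)) {
    sc_text(sc, 0.5, 0.95, spec$title, size = spec$fontsize * 1.3,
            bold = TRUE)
  }
  render_formats(sc, path, spec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

heat_palette <- function(metric) {
  if (metric == "correlation") {
    grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(101L)
  } else {
    grDevices::colorRampPalette(c("#F7FBFF", "#6BAED6", "#08306B"))(101L)
  }
}

heat_range <- function(m) {
  if (m$metric == "correlation") c(-1, 1)
  else {
    v <- range(m$values, na.rm = TRUE)
    if (v[1L] == v[2L]) v + c(-0.5, 0.5) else v
  }
}

# hclust merge tree -> list of dendrogram segments in (leaf-position,
# height) coordinates.
dendro_segments <- function(hc) {
  pos <- stats::setNames(seq_along(hc$order), hc$order)  # leaf -> x slot
  nx <- numeric(nrow(hc$merge)); nh <- numeric(nrow(hc$merge))
  segs <- list()
  node_x <- function(ch) if (ch < 0) pos[ch * -1] else nx[ch]
  node_h <- function(ch) if (ch < 0) 0 else nh[ch]
  for (kk in seq_len(nrow(hc$merge))) {
    c1 <- hc$merge[kk, 1L]; c2 <- hc$merge[kk, 2L]
    x1 <- node_x(c1); x2 <- node_x(c2)
    h <- hc$height[kk]
    segs[[length(segs) + 1L]] <- c(x1, node_h(c1), x1, h)
    segs[[length(segs) + 1L]] <- c(x2, node_h(c2), x2, h)
    segs[[length(segs) + 1L]] <- c(x1, h, x2, h)
    nx[kk] <- (x1 + x2) / 2; nh[kk] <- h
  }
  do.call(rbind, segs)
}

#' Draw a pairwise heat map
#'
#' Two styles: `"square"` (full matrix, default) and `"tribar"`
#' (lower-triangular with a marginal bar plot of set sizes, the style used
#' for symmetric statistics such as the Jaccard matrix; asymmetric
#' matrices are rejected with a pointer to the square style). Optional
#' hierarchical clustering reorders rows/columns and draws a dendrogram
#' (square style).
#'
#' @param m a [pairwise_matrix()].
#' @param spec a [figure_spec()]; `spec$extra$style` selects the style.
#' @param cluster `NULL`, or a list with elements `linkage` and `distance`
#'   passed to [hierarchical_order()].
#' @param path output path without extension.
#' @return Character vector of written file paths.
#' @export
plot_heatmap <- function(m, spec = figure_spec(), cluster = NULL,
                         path = "heatmap") {
  stopifnot(inherits(m, "pairwise_matrix"))
  style <- spec$extra$style %||% "square"
  style <- match.arg(style, c("square", "tribar"))
  n <- length(m$labels)
  v <- m$values
  if (style == "tribar" && !isTRUE(all.equal(v, t(v), tolerance = 1e-12,
                                             check.attributes = FALSE))) {
    stop("matrix is asymmetric; the triangular style needs a symmetric metric - use the square style")
  }
  ord <- seq_len(n)
  hc <- NULL
  if (!is.null(cluster)) {
    ho <- hierarchical_order(m, linkage = cluster$linkage %||% "average",
                             distance = cluster$distance %||% "euclidean")
    ord <- match(ho$order, m$labels)
    hc <- ho$hclust
  }
  v <- v[ord, ord, drop = FALSE]
  labels <- m$labels[ord]
  sizes <- m$set_sizes[ord]
  pal <- heat_palette(m$metric)
  rng <- heat_range(m)
  cell_col <- function(x) {
    if (is.na(x)) return("#BBBBBB")
    pal[1L + round(100 * (min(max(x, rng[1L]), rng[2L]) - rng[1L]) /
                     (rng[2L] - rng[1L]))]
  }
  sc <- new_scene(spec$width, spec$height)
  hx0 <- 0.22; hx1 <- 0.80
  hy0 <- 0.16; hy1 <- if (is.null(hc)) 0.80 else 0.70
  cw <- (hx1 - hx0) / n; chh <- (hy1 - hy0) / n
  cx <- hx0 + (seq_len(n) - 0.5) * cw
  cy <- hy1 - (seq_len(n) - 0.5) * chh

  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (style == "tribar" && j > i) next
    sc_rect(sc, hx0 + (j - 1) * cw, hy1 - i * chh,
            hx0 + j * cw, hy1 - (i - 1) * chh,
            fill = cell_col(v[i, j]), stroke = "white", lwd = 0.4)
    if (n <= 8L) {
      val <- v[i, j]
      sc_text(sc, cx[j], cy[i],
              if (is.na(val)) "NA" else sprintf("%.2f", val),
              size = spec$fontsize * 0.62,
              col = if (!is.na(val) && (val - rng[1L]) / (rng[2L] - rng[1L]) > 0.6)
                      "white" else "black")
    }
  }
  for (i in seq_len(n)) {
    sc_text(sc, hx0 - 0.012, cy[i], labels[i], size = spec$fontsize * 0.85,
            anchor = "end")
    sc_text(sc, cx[i], hy0 - 0.015, labels[i], size = spec$fontsize * 0.85,
            anchor = "end", angle = 40)
  }
  if (style == "tribar") {
    # marginal set-size bars above each column
    bmax <- max(sizes, 1)
    for (j in seq_len(n)) {
      h <- sizes[j] / bmax * 0.14
      sc_rect(sc, cx[j] - cw * 0.33, hy1 + 0.01, cx[j] + cw * 0.33,
              hy1 + 0.01 + h, fill = "#7F7F7F")
    }
    sc_text(sc, hx0 - 0.012, hy1 + 0.08, "Regions", anchor = "end",
            size = spec$fontsize * 0.75)
  } else if (!is.null(hc)) {
    segs <- dendro_segments(hc)
    hmax <- max(hc$height)
    dx <- function(p) hx0 + (p - 0.5) * cw
    dy <- function(h) hy1 + 0.015 + h / hmax * 0.14
    for (si in seq_len(nrow(segs))) {
      sc_segments(sc, dx(segs[si, 1L]), dy(segs[si, 2L]),
                  dx(segs[si, 3L]), dy(segs[si, 4L]), stroke = "#3B3B3B",
                  lwd = 1)
    }
  }
  # color legend
  ly0 <- hy0; ly1 <- hy1
  for (q in 0:100) {
    sc_rect(sc, 0.86, ly0 + q / 101 * (ly1 - ly0),
            0.89, ly0 + (q + 1) / 101 * (ly1 - ly0), fill = pal[q + 1L])
  }
  sc_text(sc, 0.905, ly0, format_sig(rng[1L]), anchor = "start",
          size = spec$fontsize * 0.75)
  sc_text(sc, 0.905, ly1, format_sig(rng[2L]), anchor = "start",
          size = spec$fontsize * 0.75)
  sc_text(sc, 0.875, ly1 + 0.03, m$metric, size = spec$fontsize * 0.8)
  if (nzchar(spec$title)) {
    sc_text(sc, 0.5, 0.95, spec$title, size = spec$fontsize * 1.3,
            bold = TRUE)
  }
  render_formats(sc, path, spec)
}

format_sig <- function(x) {
  if (x == floor(x)) sprintf("%.0f", x) else sprintf("%.3g", x)
}
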