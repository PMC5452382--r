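# Fixed classical-Venn layout templates for 2..6 sets. 2-3 sets use
# circles; 4-5 sets use the standard ellipse arrangements (four congruent
# ellipses in two mirrored pairs; the rotationally symmetric five-ellipse
# construction); 6 sets uses the published six-triangle Venn arrangement.
# Category label anchors are not hard-coded: they are computed once per
# template by rasterizing the shapes on a fine grid and taking the centroid
# of each of the 2^n - 1 constant-membership regions, which guarantees that
# every representable category receives exactly one label anchor.

venn_template <- function(n) {
  switch(as.character(n),
    "2" = list(shapes = list(
      list(kind = "circle", cx = 0.40, cy = 0.48, r = 0.27),
      list(kind = "circle", cx = 0.60, cy = 0.48, r = 0.27))),
    "3" = {
      ang <- c(90, 210, 330) * pi / 180
      list(shapes = lapply(ang, function(a)
        list(kind = "circle", cx = 0.5 + 0.13 * cos(a),
             cy = 0.47 + 0.13 * sin(a), r = 0.25)))
    },
    "4" = list(shapes = list(
      list(kind = "ellipse", cx = 0.350, cy = 0.400, rx = 0.36, ry = 0.225,
           rot = 140),
      list(kind = "ellipse", cx = 0.450, cy = 0.500, rx = 0.36, ry = 0.225,
           rot = 140),
      list(kind = "ellipse", cx = 0.544, cy = 0.500, rx = 0.36, ry = 0.225,
           rot = 40),
      list(kind = "ellipse", cx = 0.644, cy = 0.400, rx = 0.36, ry = 0.225,
           rot = 40))),
    "5" = list(shapes = list(
      list(kind = "ellipse", cx = 0.428, cy = 0.449, rx = 0.435, ry = 0.25,
           rot = 155),
      list(kind = "ellipse", cx = 0.469, cy = 0.543, rx = 0.435, ry = 0.25,
           rot = 82),
      list(kind = "ellipse", cx = 0.558, cy = 0.523, rx = 0.435, ry = 0.25,
           rot = 10),
      list(kind = "ellipse", cx = 0.578, cy = 0.432, rx = 0.435, ry = 0.25,
           rot = 118),
      list(kind = "ellipse", cx = 0.489, cy = 0.383, rx = 0.435, ry = 0.25,
           rot = 46))),
    "6" = list(shapes = list(
      list(kind = "triangle", x = c(0.637, 0.649, 0.188),
           y = c(0.921, 0.274, 0.667)),
      list(kind = "triangle", x = c(0.981, 0.335, 0.393),
           y = c(0.769, 0.191, 0.671)),
      list(kind = "triangle", x = c(0.941, 0.292, 0.456),
           y = c(0.397, 0.475, 0.747)),
      list(kind = "triangle", x = c(0.662, 0.316, 0.662),
           y = c(0.119, 0.548, 0.700)),
      list(kind = "triangle", x = c(0.309, 0.374, 0.681),
           y = c(0.081, 0.718, 0.488)),
      list(kind = "triangle", x = c(0.016, 0.726, 0.522),
           y = c(0.626, 0.687, 0.327)))),
    stop("Venn templates exist for 2 to 6 sets only")
  )
}

point_in_shape <- function(shape, px, py) {
  switch(shape$kind,
    circle = (px - shape$cx)^2 + (py - shape$cy)^2 <= shape$r^2,
    ellipse = {
      a <- shape$rot * pi / 180
      dx <- px - shape$cx; dy <- py - shape$cy
      u <- dx * cos(-a) - dy * sin(-a)
      v <- dx * sin(-a) + dy * cos(-a)
      (u / shape$rx)^2 + (v / shape$ry)^2 <= 1
    },
    triangle = {
      x <- shape$x; y <- shape$y
      s <- function(x1, y1, x2, y2) (px - x2) * (y1 - y2) - (x1 - x2) * (py - y2)
      d1 <- s(x[1L], y[1L], x[2L], y[2L])
      d2 <- s(x[2L], y[2L], x[3L], y[3L])
      d3 <- s(x[3L], y[3L], x[1L], y[1L])
      !((d1 < 0 | d2 < 0 | d3 < 0) & (d1 > 0 | d2 > 0 | d3 > 0))
    },
    stop("unknown shape kind")
  )
}

# Grid-sampled centroid anchors for all 2^n - 1 membership regions.
# Cached per n; a row of NAs marks a region the geometry cannot represent
# (labels for such regions fall back to a margin listing).
.venn_anchor_cache <- new.env(parent = emptyenv())

venn_anchors <- function(n, grid_n = 441L) {
  key <- as.character(n)
  if (!is.null(.venn_anchor_cache[[key]])) return(.venn_anchor_cache[[key]])
  tpl <- venn_template(n)
  gx <- seq(0.001, 0.999, length.out = grid_n)
  pts <- expand.grid(x = gx, y = gx)
  mask <- numeric(nrow(pts))
  for (i in seq_len(n)) {
    mask <- mask + point_in_shape(tpl$shapes[[i]], pts$x, pts$y) * 2^(i - 1)
  }
  anchors <- matrix(NA_real_, 2^n - 1, 2L)
  for (mk in seq_len(2^n - 1)) {
    sel <- mask == mk
    if (any(sel)) {
      # centroid of the region's largest connected blob approximated by
      # trimming to the densest quantile box keeps anchors inside thin
      # lens-shaped regions
      xs <- pts$x[sel]; ys <- pts$y[sel]
      anchors[mk, ] <- c(stats::median(xs), stats::median(ys))
      if (!point_region_ok(tpl, n, anchors[mk, 1L], anchors[mk, 2L], mk)) {
        # median fell outside (non-convex region): pick the in-region
        # sample closest to the centroid
        cxy <- c(mean(xs), mean(ys))
        d2 <- (xs - cxy[1L])^2 + (ys - cxy[2L])^2
        j <- which.min(d2)
        anchors[mk, ] <- c(xs[j], ys[j])
      }
    }
  }
  .venn_anchor_cache[[key]] <- list(template = tpl, anchors = anchors)
  .venn_anchor_cache[[key]]
}

point_region_ok <- function(tpl, n, px, py, mk) {
  m <- 0
  for (i in seq_len(n)) {
    m <- m + point_in_shape(tpl$shapes[[i]], px, py) * 2^(i - 1)
  }
  m == mk
}

# Anchor for each set's name label: pushed outward from the diagram
# centroid past the shape centre, clamped to the canvas.
venn_setlabel_anchors <- function(n) {
  tpl <- venn_template(n)
  ctr <- vapply(tpl$shapes, function(s) {
    if (s$kind == "triangle") c(mean(s$x), mean(s$y)) else c(s$cx, s$cy)
  }, numeric(2L))
  C <- rowMeans(ctr)
  out <- matrix(0, n, 2L)
  for (i in seq_len(n)) {
    d <- ctr[, i] - C
    nd <- sqrt(sum(d^2))
    if (nd < 1e-9) d <- c(0, 1) else d <- d / nd
    if (tpl$shapes[[i]]$kind == "triangle") {
      # label beyond the vertex farthest from the diagram centre
      vx <- tpl$shapes[[i]]$x; vy <- tpl$shapes[[i]]$y
      j <- which.max((vx - C[1L])^2 + (vy - C[2L])^2)
      p <- c(vx[j], vy[j]) + d * 0.05
    } else {
      p <- ctr[, i] + d * (if (n <= 3) 0.33 else 0.42)
    }
    out[i, ] <- pmin(pmax(p, 0.06), 0.94)
  }
  out
}
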