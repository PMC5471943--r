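# Deterministic SVG emission: fixed 2-decimal coordinate precision,
# stable element ordering, no timestamps -- identical inputs give
# byte-identical documents.

svg_num <- function(x) {
  x <- round(x, 2)
  x[x == 0] <- 0
  formatC(x, format = "f", digits = 2)
}

new_svg_doc <- function(width, height, body, scene = NULL) {
  structure(list(width = width, height = height, body = body, scene = scene),
            class = "svg_doc")
}

#' @export
as.character.svg_doc <- function(x, ...) {
  paste0(c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" ",
                   "xmlns:xlink=\"http://www.w3.org/1999/xlink\" ",
                   "width=\"%s\" height=\"%s\" viewBox=\"0 0 %s %s\">"),
            svg_num(x$width), svg_num(x$height),
            svg_num(x$width), svg_num(x$height)),
    x$body,
    "</svg>"), collapse = "\n")
}

#' @export
print.svg_doc <- function(x, ...) {
  cat(sprintf("<svg_doc> %s x %s px, %d element line(s)\n",
              svg_num(x$width), svg_num(x$height), length(x$body)))
  invisible(x)
}

#' Write an SVG document (and optionally its geometry scene) to disk
#'
#' @param doc An `svg_doc` from one of the renderers.
#' @param path Output `.svg` path.
#' @param scene_path Optional path for a JSON dump of the computed
#'   geometry (blocks, ribbons, glyphs), for downstream testing.
#' @return `path`, invisibly.
#' @export
write_svg <- function(doc, path, scene_path = NULL) {
  writeLines(as.character(doc), path)
  if (!is.null(scene_path)) {
    jsonlite::write_json(doc$scene, scene_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

svg_rect <- function(x, y, w, h, fill, opacity = NULL, stroke = NULL) {
  sprintf("<rect x=\"%s\" y=\"%s\" width=\"%s\" height=\"%s\" fill=\"%s\"%s%s/>",
          svg_num(x), svg_num(y), svg_num(w), svg_num(h), fill,
          if (is.null(opacity)) "" else sprintf(" fill-opacity=\"%s\"", svg_num(opacity)),
          if (is.null(stroke)) "" else sprintf(" stroke=\"%s\" stroke-width=\"0.50\"", stroke))
}

# Ribbon between vertical segments [ys0,ys1] at xs and [yk0,yk1] at xk,
# as two cubic Beziers with control points at the horizontal midpoint.
svg_ribbon <- function(xs, ys0, ys1, xk, yk0, yk1, fill, opacity = 0.5) {
  mx <- (xs + xk) / 2
  sprintf(paste0("<path d=\"M %s %s C %s %s %s %s %s %s L %s %s ",
                 "C %s %s %s %s %s %s Z\" fill=\"%s\" fill-opacity=\"%s\"/>"),
          svg_num(xs), svg_num(ys0),
          svg_num(mx), svg_num(ys0), svg_num(mx), svg_num(yk0),
          svg_num(xk), svg_num(yk0),
          svg_num(xk), svg_num(yk1),
          svg_num(mx), svg_num(yk1), svg_num(mx), svg_num(ys1),
          svg_num(xs), svg_num(ys1),
          fill, svg_num(opacity))
}

# Alluvial geometry for a rectangular region; shared by the standalone
# alluvial renderer and the composed electrode-view figure.
alluvial_geometry <- function(dcs, ordering, x0, y0, w, h) {
  ts <- ordering$timesteps
  tt <- length(ts)
  n_total <- sum(sizes_at(dcs, ts[1]))
  spacing <- w / tt
  bw <- min(20, 0.3 * spacing)
  sy <- h / n_total
  xs <- x0 + (seq_len(tt) - 1L) * spacing + (spacing - bw) / 2

  blocks <- bind_rows(lapply(seq_along(ts), function(k) {
    b <- dcs$blocks[dcs$blocks$t == ts[k], ]
    b <- b[order(b$index), ]
    tibble(t = ts[k], index = b$index, persistent_id = b$persistent_id,
           x = xs[k], y = y0 + ordering$offsets[[k]] * sy,
           w = bw, h = b$size * sy,
           color = unname(dcs$colors[b$persistent_id]))
  }))

  links <- list()
  for (k in seq_along(ts)[-length(ts)]) {
    lk <- dcs$links[dcs$links$t == ts[k], ]
    if (nrow(lk) == 0) next
    bsrc <- blocks[blocks$t == ts[k], ]
    bsnk <- blocks[blocks$t == ts[k + 1], ]
    csrc <- bsrc$y + bsrc$h / 2
    csnk <- bsnk$y + bsnk$h / 2
    # slot links within each source block by sink vertical position,
    # and within each sink block by source vertical position
    lk <- lk[order(lk$source, csnk[lk$sink + 1L], lk$sink), ]
    lk$ys0 <- NA_real_
    for (i in unique(lk$source)) {
      sel <- lk$source == i
      tops <- bsrc$y[i + 1L] + cumsum(c(0, head(lk$count[sel], -1))) * sy
      lk$ys0[sel] <- tops
    }
    lk <- lk[order(lk$sink, csrc[lk$source + 1L], lk$source), ]
    lk$yk0 <- NA_real_
    for (j in unique(lk$sink)) {
      sel <- lk$sink == j
      tops <- bsnk$y[j + 1L] + cumsum(c(0, head(lk$count[sel], -1))) * sy
      lk$yk0[sel] <- tops
    }
    lk <- lk[order(lk$source, lk$sink), ]
    links[[length(links) + 1L]] <- tibble(
      t = ts[k], source = lk$source, sink = lk$sink, count = lk$count,
      xs = xs[k] + bw, ys0 = lk$ys0, ys1 = lk$ys0 + lk$count * sy,
      xk = xs[k + 1], yk0 = lk$yk0, yk1 = lk$yk0 + lk$count * sy,
      color = unname(dcs$colors[lk$source_id]))
  }
  list(blocks = blocks,
       links = if (length(links)) bind_rows(links) else NULL)
}

alluvial_elements <- function(geom) {
  out <- character(0)
  if (!is.null(geom$links)) {
    out <- c(out, vapply(seq_len(nrow(geom$links)), function(r) {
      l <- geom$links[r, ]
      svg_ribbon(l$xs, l$ys0, l$ys1, l$xk, l$yk0, l$yk1, l$color)
    }, character(1)))
  }
  c(out, vapply(seq_len(nrow(geom$blocks)), function(r) {
    b <- geom$blocks[r, ]
    svg_rect(b$x, b$y, b$w, b$h, b$color)
  }, character(1)))
}

#' Render the alluvial cluster-evolution view to SVG
#'
#' Per timestep, a vertical stack of rectangles (height proportional to
#' community size, fill the community color); per transition link, a
#' cubic Bezier ribbon of thickness proportional to its electrode count.
#' Output is deterministic: identical inputs give byte-identical SVG.
#'
#' @param dcs A `dyncomm_set` (see [track_communities()]).
#' @param ordering A `timeline_ordering` from [barycenter_order()].
#' @param width,height Canvas size in px.
#' @param margin Outer margin in px.
#' @return An `svg_doc`; its `scene` element carries the computed
#'   geometry.
#' @export
render_alluvial <- function(dcs, ordering, width = 960, height = 540,
                            margin = 20) {
  if (width <= 0 || height <= 0) abort("Canvas must have positive size.")
  geom <- alluvial_geometry(dcs, ordering, margin, margin,
                            width - 2 * margin, height - 2 * margin)
  new_svg_doc(width, height, alluvial_elements(geom), scene = geom)
}

#' Render the K-cluster likelihood heatmap to SVG
#'
#' A timestep-by-K grid; cell grayscale encodes likelihood (black =
#' likelihood 1, white = 0). A timestep whose profile is all zero (the
#' degenerate K = 1 case) renders as a fully white column.
#'
#' @param profiles A tibble with columns `t`, `k`, `likelihood` (e.g.
#'   [k_profiles()] output or the `profiles` element of a `dyncomm_set`).
#' @param cell_w,cell_h Cell size in px.
#' @param margin Outer margin in px.
#' @return An `svg_doc` with the cell geometry as its `scene`.
#' @export
render_k_heatmap <- function(profiles, cell_w = 14, cell_h = 14, margin = 2) {
  profiles <- as_tibble(profiles)[, c("t", "k", "likelihood")]
  ts <- sort(unique(profiles$t))
  ks <- sort(unique(profiles$k))
  profiles <- arrange(profiles, .data$t, .data$k)
  cells <- mutate(profiles,
                  x = margin + (match(.data$t, ts) - 1L) * cell_w,
                  y = margin + (match(.data$k, ks) - 1L) * cell_h,
                  fill = grDevices::rgb(1 - .data$likelihood,
                                        1 - .data$likelihood,
                                        1 - .data$likelihood))
  body <- vapply(seq_len(nrow(cells)), function(r) {
    svg_rect(cells$x[r], cells$y[r], cell_w, cell_h, cells$fill[r],
             stroke = "#cccccc")
  }, character(1))
  new_svg_doc(2 * margin + length(ts) * cell_w,
              2 * margin + length(ks) * cell_h,
              body, scene = cells)
}

# Clock-glyph slices for one electrode at (cx, cy), radius r. SVG y
# points down, so increasing angle from -90 degrees sweeps clockwise on
# screen, starting at 12 o'clock.
glyph_elements <- function(cx, cy, r, colors, opacities) {
  n <- length(colors)
  if (n == 1) {
    return(sprintf(
      "<circle cx=\"%s\" cy=\"%s\" r=\"%s\" fill=\"%s\" fill-opacity=\"%s\" stroke=\"#444444\" stroke-width=\"0.50\"/>",
      svg_num(cx), svg_num(cy), svg_num(r), colors, svg_num(opacities)))
  }
  a <- -pi / 2 + 2 * pi * (0:n) / n
  vapply(seq_len(n), function(j) {
    x0 <- cx + r * cos(a[j]);     y0 <- cy + r * sin(a[j])
    x1 <- cx + r * cos(a[j + 1]); y1 <- cy + r * sin(a[j + 1])
    large <- if ((a[j + 1] - a[j]) > pi) 1 else 0
    sprintf(paste0("<path d=\"M %s %s L %s %s A %s %s 0 %d 1 %s %s Z\" ",
                   "fill=\"%s\" fill-opacity=\"%s\" stroke=\"#444444\" stroke-width=\"0.50\"/>"),
            svg_num(cx), svg_num(cy), svg_num(x0), svg_num(y0),
            svg_num(r), svg_num(r), large, svg_num(x1), svg_num(y1),
            colors[j], svg_num(opacities[j]))
  }, character(1))
}

# Affine map of layout coordinates into a view box: uniform scale
# (relative distances preserved) plus centering.
view_transform <- function(coords, crop, w, h, pad) {
  xr <- if (is.null(crop)) range(coords$x) else crop[c(1, 3)]
  yr <- if (is.null(crop)) range(coords$y) else crop[c(2, 4)]
  dx <- max(xr[2] - xr[1], 1e-9); dy <- max(yr[2] - yr[1], 1e-9)
  s <- min((w - 2 * pad) / dx, (h - 2 * pad) / dy)
  ox <- (w - s * dx) / 2
  oy <- (h - s * dy) / 2
  list(s = s,
       fx = function(x) ox + s * (x - xr[1]),
       fy = function(y) oy + s * (y - yr[1]))
}

#' Render the composed electrode-view figure to SVG
#'
#' Electrode views (clock-glyph small multiples, one per aggregated
#' timestep span) alternate above and below a central alluvial
#' cluster-evolution band, left-to-right in timeline order; widths come
#' from the expansion-factor model (see [expansion_factor()]).
#'
#' @param dcs A `dyncomm_set`.
#' @param ordering A `timeline_ordering`.
#' @param activation An [activation_series()].
#' @param layout An [electrode_layout()] covering all electrodes.
#' @param granularity Timesteps aggregated per electrode view.
#' @param w_max,w_min,c Width model parameters (see
#'   [expansion_factor()]).
#' @param view_height Height of each electrode view in px (defaults to
#'   the computed view width, i.e. square views).
#' @param band_height Height of the central alluvial band in px.
#' @param glyph_scale Glyph radius as a fraction of the nearest
#'   electrode spacing.
#' @return An `svg_doc` with per-view and per-glyph geometry as `scene`.
#' @export
render_electrode_views <- function(dcs, ordering, activation, layout,
                                   granularity, w_max = 960, w_min = 120,
                                   c = 1, view_height = NULL,
                                   band_height = 160, glyph_scale = 0.4) {
  check_layout_covers(layout, dcs$node_ids)
  ts <- ordering$timesteps
  plan <- plan_views(length(ts), granularity)
  n_x1 <- sum(plan$axis == "x1"); n_x2 <- sum(plan$axis == "x2")
  ef <- expansion_factor(n_x1, n_x2, w_max, w_min, c)
  widths <- ef$w_i * plan$width_share
  x_off <- cumsum(c(0, head(widths, -1)))
  vh <- view_height %||% ef$w_i
  total_w <- sum(widths)
  total_h <- 2 * vh + band_height

  coords <- layout$coordinates
  nn <- nearest_spacing(coords)
  body <- character(0)

  # central alluvial band spanning the full figure width
  geom <- alluvial_geometry(dcs, ordering, 0, vh, total_w, band_height)
  body <- c(body, alluvial_elements(geom))

  glyph_scenes <- list()
  for (v in seq_len(nrow(plan))) {
    w_v <- widths[v]
    y_v <- if (plan$axis[v] == "x1") 0 else vh + band_height
    tr <- view_transform(coords, layout$crop_region, w_v, vh, pad = w_v * 0.08)
    r <- glyph_scale * nn * tr$s
    body <- c(body, svg_rect(x_off[v], y_v, w_v, vh, "none", stroke = "#888888"))
    if (!is.null(layout$background_image)) {
      body <- c(body, sprintf(
        "<image x=\"%s\" y=\"%s\" width=\"%s\" height=\"%s\" xlink:href=\"%s\"/>",
        svg_num(x_off[v]), svg_num(y_v), svg_num(w_v), svg_num(vh),
        layout$background_image))
    }
    glyphs <- aggregate_glyphs(dcs, activation,
                               timesteps = ts[(plan$from[v] + 1L):plan$to[v]])
    n_slices <- plan$to[v] - plan$from[v]
    for (id in sort(unique(glyphs$node))) {
      g <- glyphs[glyphs$node == id, ]
      g <- g[order(g$slice), ]
      row <- coords[coords$id == id, ]
      cx <- x_off[v] + tr$fx(row$x)
      cy <- y_v + tr$fy(row$y)
      body <- c(body, glyph_elements(cx, cy, r, g$color, g$opacity))
      glyph_scenes[[length(glyph_scenes) + 1L]] <-
        tibble(view = plan$view[v], node = id, cx = cx, cy = cy, r = r,
               n_slices = n_slices)
    }
  }
  scene <- list(plan = mutate(plan, width = widths, x = x_off),
                expansion = ef,
                glyphs = bind_rows(glyph_scenes),
                band = geom)
  new_svg_doc(total_w, total_h, body, scene = scene)
}

# Smallest nearest-neighbor distance among electrode coordinates
# (layout units); glyph radii scale from it.
nearest_spacing <- function(coords) {
  n <- nrow(coords)
  if (n < 2) return(1)
  d <- as.matrix(stats::dist(coords[, c("x", "y")]))
  diag(d) <- Inf
  m <- min(d)
  if (!is.finite(m) || m <= 0) 1 else m
}
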