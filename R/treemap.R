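#' Squarified treemap layout of a shape profile
#'
#' Lays the sub-hierarchies of a profile out as rectangles tiling a canvas,
#' with areas proportional to class counts — the standard way of visualizing
#' an ontology's shape at a glance. The squarified algorithm (Bruls, Huizing
#' & van Wijk) is used: sub-hierarchies are placed in decreasing count order
#' in rows along the shorter side of the remaining canvas, closing a row as
#' soon as adding the next item would worsen the worst aspect ratio.
#'
#' @param profile a `shape_profile` with `total > 0`.
#' @param canvas numeric `c(width, height)`, both positive.
#' @return A `treemap_layout`: list with `rectangles` (data frame with
#'   columns `subhierarchy`, `x`, `y`, `width`, `height`, `shade`) and
#'   `canvas`. `x`,`y` is the lower-left corner; `shade` in (0, 1] increases
#'   monotonically with count (darker = more classes). Zero-count
#'   sub-hierarchies get no rectangle.
#' @export
treemap_layout <- function(profile, canvas = c(4, 3)) {
  stopifnot(inherits(profile, "shape_profile"))
  check(is.numeric(canvas) && length(canvas) == 2L && all(canvas > 0),
        "'canvas' must be two positive numbers (width, height)")
  counts <- profile$counts[profile$counts > 0L]
  check(length(counts) > 0L, "profile has no positive counts")
  ord <- order(-as.numeric(counts), names(counts))
  counts <- counts[ord]
  W <- canvas[[1L]]; H <- canvas[[2L]]
  areas <- as.numeric(counts) / sum(counts) * (W * H)

  rects <- vector("list", length(areas))
  x0 <- 0; y0 <- 0; w <- W; h <- H
  i <- 1L
  n <- length(areas)
  while (i <= n) {
    side <- min(w, h)
    # grow the row while the worst aspect ratio does not degrade
    row <- areas[i]
    best <- squarify_worst(row, side)
    j <- i + 1L
    while (j <= n) {
      cand <- c(row, areas[j])
      wr <- squarify_worst(cand, side)
      if (wr <= best) { row <- cand; best <- wr; j <- j + 1L } else break
    }
    thick <- sum(row) / side
    off <- 0
    for (k in seq_along(row)) {
      len <- row[k] / thick
      idx <- i + k - 1L
      if (w <= h) {
        # row along the bottom, items left to right
        rects[[idx]] <- list(names(counts)[idx], x0 + off, y0, len, thick)
      } else {
        # column along the left, items bottom to top
        rects[[idx]] <- list(names(counts)[idx], x0, y0 + off, thick, len)
      }
      off <- off + len
    }
    if (w <= h) { y0 <- y0 + thick; h <- h - thick } else { x0 <- x0 + thick; w <- w - thick }
    i <- i + length(row)
  }

  df <- data.frame(subhierarchy = vapply(rects, `[[`, "", 1L),
                   x = vapply(rects, `[[`, 0, 2L),
                   y = vapply(rects, `[[`, 0, 3L),
                   width = vapply(rects, `[[`, 0, 4L),
                   height = vapply(rects, `[[`, 0, 5L),
                   stringsAsFactors = FALSE)
  df$shade <- 0.25 + 0.75 * as.numeric(counts) / max(as.numeric(counts))
  structure(list(rectangles = df, canvas = c(width = W, height = H)),
            class = "treemap_layout")
}

# worst aspect ratio of a row of areas laid against a side of given length
squarify_worst <- function(row, side) {
  thick <- sum(row) / side
  lens <- row / thick
  max(pmax(lens / thick, thick / lens))
}

#' @export
print.treemap_layout <- function(x, ...) {
  cat(sprintf("<treemap_layout> %d rectangles on a %g x %g canvas\n",
              nrow(x$rectangles), x$canvas[["width"]], x$canvas[["height"]]))
  invisible(x)
}

#' Plot a treemap layout
#'
#' Base-graphics rendering: grey rectangles (darker = larger sub-hierarchy)
#' with id labels where the rectangle is large enough to hold them.
#'
#' @param x a `treemap_layout`.
#' @param main plot title.
#' @param ... ignored.
#' @return Invisibly, `x`.
#' @export
plot.treemap_layout <- function(x, main = "", ...) {
  r <- x$rectangles
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, x$canvas[["width"]]),
                        ylim = c(0, x$canvas[["height"]]), asp = 1)
  graphics::title(main = main)
  graphics::rect(r$x, r$y, r$x + r$width, r$y + r$height,
                 col = grDevices::grey(1 - 0.7 * r$shade), border = "white")
  big <- r$width * r$height >= 0.02 * prod(x$canvas)
  if (any(big)) {
    graphics::text(r$x[big] + r$width[big] / 2, r$y[big] + r$height[big] / 2,
                   labels = r$subhierarchy[big], cex = 0.7)
  }
  invisible(x)
}

#' Export a treemap layout as SVG
#'
#' Writes a standalone SVG file with one `<rect>` per sub-hierarchy (greyscale
#' fill by count) and a centred label for the larger rectangles.
#'
#' @param layout a `treemap_layout`.
#' @param path output file path.
#' @param scale pixels per canvas unit.
#' @return Invisibly, `path`.
#' @export
export_treemap_svg <- function(layout, path, scale = 100) {
  stopifnot(inherits(layout, "treemap_layout"))
  W <- layout$canvas[["width"]] * scale
  H <- layout$canvas[["height"]] * scale
  r <- layout$rectangles
  esc <- function(s) gsub("&", "&amp;", gsub("<", "&lt;", s, fixed = TRUE), fixed = TRUE)
  lines <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%g" height="%g" viewBox="0 0 %g %g">', W, H, W, H))
  for (i in seq_len(nrow(r))) {
    g <- round(255 * (1 - 0.7 * r$shade[i]))
    # SVG y axis points down: flip
    lines <- c(lines, sprintf(
      '  <rect x="%.3f" y="%.3f" width="%.3f" height="%.3f" fill="rgb(%d,%d,%d)" stroke="white"/>',
      r$x[i] * scale, H - (r$y[i] + r$height[i]) * scale,
      r$width[i] * scale, r$height[i] * scale, g, g, g))
    if (r$width[i] * r$height[i] >= 0.02 * prod(layout$canvas)) {
      lines <- c(lines, sprintf(
        '  <text x="%.3f" y="%.3f" font-size="%.1f" text-anchor="middle">%s</text>',
        (r$x[i] + r$width[i] / 2) * scale,
        H - (r$y[i] + r$height[i] / 2) * scale,
        0.12 * scale, esc(r$subhierarchy[i])))
    }
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, path)
  invisible(path)
}
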