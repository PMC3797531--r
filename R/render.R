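## SVG rendering ----------------------------------------------------------

#' Render a per-cell field as a filled-polygon SVG map
#'
#' Reproduces the standard tissue concentration map: each cell polygon
#' filled on a monotone white-to-dark-blue scale (white = 0 / minimum,
#' dark blue = maximum).  The SVG is written as plain text, so identical
#' inputs give byte-identical files.
#'
#' @param t A `tissue`.
#' @param field Per-cell values (length = cell count).
#' @param path Output `.svg` path.
#' @param width Image width in pixels (height follows the aspect ratio).
#' @param zlim Value range mapped onto the colour scale (default
#'   `c(min(0, field), max(field))`).
#' @param stroke Wall colour.
#' @return `path`, invisibly.
#' @export
render_tissue <- function(t, field, path, width = 480,
                          zlim = NULL, stroke = "#555555") {
  stopifnot(length(field) == n_cells(t))
  zlim <- zlim %||% c(min(0, field), max(field))
  if (zlim[2L] <= zlim[1L]) zlim[2L] <- zlim[1L] + 1
  z <- pmin(pmax((field - zlim[1L]) / (zlim[2L] - zlim[1L]), 0), 1)
  ## white (255,255,255) -> dark blue (0,0,139)
  col <- sprintf("#%02x%02x%02x", round(255 * (1 - z)),
                 round(255 * (1 - z)), round(255 - 116 * z))
  xr <- range(t$V[, 1L]); yr <- range(t$V[, 2L])
  pad <- 0.02 * max(diff(xr), diff(yr))
  xr <- xr + c(-pad, pad); yr <- yr + c(-pad, pad)
  sc <- width / diff(xr)
  height <- ceiling(diff(yr) * sc)
  px <- function(x) formatC((x - xr[1L]) * sc, format = "f", digits = 2)
  py <- function(y) formatC((yr[2L] - y) * sc, format = "f", digits = 2)
  lines <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
    width, height, width, height))
  for (ci in seq_len(n_cells(t))) {
    P <- cell_polygon(t, ci)
    pts <- paste(px(P[, 1L]), py(P[, 2L]), sep = ",", collapse = " ")
    lines <- c(lines, sprintf(
      '<polygon points="%s" fill="%s" stroke="%s" stroke-width="1"/>',
      pts, col[ci], stroke))
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, path)
  invisible(path)
}
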