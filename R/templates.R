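## Tissue templates ------------------------------------------------------

#' Hexagonal tissue template
#'
#' A centred hexagonal array of regular hexagonal cells: one central cell
#' surrounded by `rings` shells, giving \eqn{3r(r+1)+1} cells in total.
#'
#' @param rings Number of shells around the central cell (>= 0).
#' @param side Hexagon side length (= circumradius of each cell).
#' @return A `tissue` of identical regular hexagons.
#' @examples
#' nrow_cells <- n_cells(hex_template(2))   # 19
#' @export
hex_template <- function(rings, side = 1) {
  stopifnot(rings >= 0, side > 0)
  ## axial coordinates of a centred hex array (pointy-top cells)
  centers <- list()
  for (q in -rings:rings) {
    r1 <- max(-rings, -q - rings); r2 <- min(rings, -q + rings)
    for (r in r1:r2) centers[[length(centers) + 1L]] <- c(q, r)
  }
  ax <- do.call(rbind, centers)
  cx <- side * sqrt(3) * (ax[, 1L] + ax[, 2L] / 2)
  cy <- side * 1.5 * ax[, 2L]
  ang <- pi / 6 + (0:5) * pi / 3   # pointy-top hexagon corners
  polys <- lapply(seq_len(nrow(ax)), function(i)
    cbind(cx[i] + side * cos(ang), cy[i] + side * sin(ang)))
  tissue_from_polygons(polys, tol = 1e-6 * side)
}

## Region polygons -------------------------------------------------------

region_polygon <- function(region, radius = 1, a = 1, h = 1,
                           poly = NULL, segments = 96L) {
  if (is.matrix(region)) return(region)
  switch(region,
    circle = {
      th <- seq(0, 2 * pi, length.out = segments + 1L)[-(segments + 1L)]
      cbind(radius * cos(th), radius * sin(th))
    },
    semicircle = {
      th <- seq(0, pi, length.out = segments + 1L)
      rbind(cbind(radius * cos(th), radius * sin(th)))
    },
    parabola = {
      ## {(x, y): y >= a x^2, y <= h}; the closing segment from the last
      ## boundary point (xm, h) back to the first (-xm, h) is the flat top
      xm <- sqrt(h / a)
      x <- seq(-xm, xm, length.out = segments + 1L)
      cbind(x, a * x^2)
    },
    polygon = {
      if (is.null(poly)) stop_tessella("user region needs a polygon")
      poly
    },
    stop_tessella("unknown region '%s'", region))
}

## Clip a convex-or-simple polygon by the half-plane {x : a.x <= b}
## (Sutherland-Hodgman step).
clip_halfplane <- function(P, a, b) {
  n <- nrow(P)
  if (n == 0L) return(P)
  d <- P %*% a - b
  out <- matrix(0, n + 4L, 2L)
  m <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    din <- d[i] <= 0; djn <- d[j] <= 0
    if (din) { m <- m + 1L; out[m, ] <- P[i, ] }
    if (xor(din, djn)) {
      s <- d[i] / (d[i] - d[j])
      m <- m + 1L
      out[m, ] <- P[i, ] + s * (P[j, ] - P[i, ])
    }
  }
  out[seq_len(m), , drop = FALSE]
}

point_in_polygon <- function(pt, P) {
  n <- nrow(P)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((P[i, 2L] > pt[2L]) != (P[j, 2L] > pt[2L]) &&
        pt[1L] < (P[j, 1L] - P[i, 1L]) * (pt[2L] - P[i, 2L]) /
          (P[j, 2L] - P[i, 2L]) + P[i, 1L])
      inside <- !inside
    j <- i
  }
  inside
}

sample_in_region <- function(n, P, rng_ok = TRUE) {
  lo <- apply(P, 2L, min); hi <- apply(P, 2L, max)
  out <- matrix(0, 0L, 2L)
  guard <- 0L
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 16L)
    cand <- cbind(stats::runif(m, lo[1L], hi[1L]),
                  stats::runif(m, lo[2L], hi[2L]))
    keep <- apply(cand, 1L, point_in_polygon, P = P)
    out <- rbind(out, cand[keep, , drop = FALSE])
    guard <- guard + 1L
    if (guard > 10000L) stop_tessella("region sampling failed")
  }
  out[seq_len(n), , drop = FALSE]
}

#' Voronoi tissue template
#'
#' Tessellates a region with the Voronoi cells of `n_centers` uniformly
#' random interior points, clipped to the region boundary: exactly one
#' cell per center, and the cells partition the (polygonalised) region.
#' Cells are built by half-plane clipping against perpendicular bisectors,
#' visiting other centers nearest-first with the standard distance cutoff
#' (a center farther than twice the current max vertex distance cannot
#' alter the cell).
#'
#' @param region `"circle"`, `"semicircle"` (upper half-disk),
#'   `"parabola"` (the set `y >= a*x^2, y <= h`), `"polygon"` (supply
#'   `poly`), or directly a k x 2 boundary matrix.
#' @param n_centers Number of Voronoi centers (>= 1).
#' @param seed Optional RNG seed for reproducible center placement.
#' @param radius,a,h,poly Region shape parameters.
#' @param centers Optional user-supplied center coordinates (overrides
#'   random placement; rows outside the region are an error).
#' @param segments Number of segments used to polygonalise curved region
#'   boundaries.
#' @return A `tissue`; cell `i` contains center `i`.
#' @examples
#' t <- voronoi_template("circle", 25, seed = 1)
#' n_cells(t)   # 25
#' @export
voronoi_template <- function(region, n_centers, seed = NULL, radius = 1,
                             a = 1, h = 1, poly = NULL, centers = NULL,
                             segments = 96L) {
  stopifnot(n_centers >= 1L)
  P <- region_polygon(region, radius, a, h, poly, segments)
  if (signed_area(P) < 0) P <- P[rev(seq_len(nrow(P))), , drop = FALSE]
  if (!is.null(seed)) set.seed(seed)
  if (is.null(centers)) {
    centers <- sample_in_region(n_centers, P)
  } else {
    centers <- as.matrix(centers)
    stopifnot(nrow(centers) == n_centers)
    ok <- apply(centers, 1L, point_in_polygon, P = P)
    if (!all(ok))
      stop_tessella("user centers outside region: %s",
                    paste(which(!ok), collapse = ","))
  }
  ## retry-with-jitter guard for degenerate (e.g. collinear/duplicate)
  ## center sets that produce sliver or empty cells
  for (attempt in 1:5) {
    polys <- try(voronoi_cells(centers, P), silent = TRUE)
    if (!inherits(polys, "try-error")) break
    message("voronoi_template: degenerate centers, jittering (attempt ",
            attempt, ")")
    scale <- 1e-8 * max(apply(P, 2L, function(z) diff(range(z))))
    centers <- centers + matrix(stats::rnorm(length(centers), 0, scale),
                                ncol = 2L)
  }
  if (inherits(polys, "try-error")) stop(attr(polys, "condition"))
  tissue_from_polygons(polys,
                       tol = 1e-9 * max(apply(P, 2L, function(z)
                         diff(range(z)))))
}

voronoi_cells <- function(centers, P) {
  n <- nrow(centers)
  if (n == 1L) return(list(P))
  polys <- vector("list", n)
  for (i in seq_len(n)) {
    ci <- centers[i, ]
    d2 <- (centers[, 1L] - ci[1L])^2 + (centers[, 2L] - ci[2L])^2
    ord <- order(d2)
    ord <- ord[ord != i]
    cell <- P
    for (j in ord) {
      ## cutoff: farther centers cannot cut the cell any more
      maxr2 <- max((cell[, 1L] - ci[1L])^2 + (cell[, 2L] - ci[2L])^2)
      if (d2[j] > 4 * maxr2) break
      mid <- (ci + centers[j, ]) / 2
      nrm <- centers[j, ] - ci
      cell <- clip_halfplane(cell, nrm, sum(nrm * mid))
      if (nrow(cell) < 3L)
        stop_tessella("degenerate Voronoi cell for center %d", i)
    }
    area <- abs(signed_area(cell))
    if (area <= 1e-12)
      stop_tessella("degenerate Voronoi cell for center %d", i)
    polys[[i]] <- cell
  }
  polys
}
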