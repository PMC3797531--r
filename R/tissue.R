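## Tissue data structure -------------------------------------------------
##
## A tissue is a polygonal lattice: V (vertex coordinates), E (edges as
## vertex-index pairs), C (cells as ordered edge-index loops).  Indices are
## 0-based in CSV files and 1-based internally (R convention); the loaders
## convert losslessly.  Cell winding is normalised counter-clockwise.

#' Construct a tissue mesh
#'
#' @param V Numeric n x 2 matrix of vertex coordinates.
#' @param E Integer m x 2 matrix of edges (vertex index pairs, 1-based).
#' @param C List of cells, each an ordered integer vector of edge indices
#'   tracing a closed simple polygon.
#' @param validate Run full validation (chain closure, simplicity,
#'   positive areas, edge sharing).
#' @return An object of class `tissue` with elements `V`, `E`, `C`.
#' @seealso [compute_geometry()], [read_tissue()], [hex_template()]
#' @export
tissue <- function(V, E, C, validate = TRUE) {
  V <- as.matrix(V); storage.mode(V) <- "double"
  E <- as.matrix(E); storage.mode(E) <- "integer"
  if (ncol(V) != 2L) stop_tessella("V must be an n x 2 matrix")
  if (length(E) && ncol(E) != 2L) stop_tessella("E must be an m x 2 matrix")
  t <- structure(list(V = V, E = E, C = lapply(C, as.integer)),
                 class = "tissue")
  t <- normalize_winding(t)
  if (validate) validate_tissue(t)
  t
}

#' @export
print.tissue <- function(x, ...) {
  cat("<tissue: ", nrow(x$V), " vertices, ", nrow(x$E), " edges, ",
      length(x$C), " cells>\n", sep = "")
  invisible(x)
}

#' Number of cells in a tissue
#' @param t A `tissue`.
#' @return Integer count.
#' @export
n_cells <- function(t) length(t$C)

## Ordered vertex loop of one cell from its ordered edge list.
## Edge k in the loop connects loop[k] -> loop[k+1] (cyclically).
cell_loop_vertices <- function(t, ci) {
  ed <- t$C[[ci]]
  k <- length(ed)
  if (k < 3L)
    stop_tessella("cell %d has fewer than 3 edges", ci)
  if (any(ed < 1L | ed > nrow(t$E)))
    stop_tessella("cell %d: dangling edge index", ci)
  E <- t$E
  loop <- integer(k)
  e1 <- E[ed[1L], ]; e2 <- E[ed[2L], ]
  shared <- intersect(e1, e2)
  if (length(shared) != 1L)
    stop_tessella("cell %d: consecutive edges 1,2 share %d vertices",
                  ci, length(shared))
  loop[1L] <- setdiff(e1, shared)
  loop[2L] <- shared
  for (j in 3:k) {
    ej <- E[ed[j - 1L], ]
    nxt <- setdiff(ej, loop[j - 1L])
    if (length(nxt) != 1L || !(loop[j - 1L] %in% ej))
      stop_tessella("cell %d: open chain at edge position %d", ci, j - 1L)
    loop[j] <- nxt
  }
  ## closure: last edge must connect loop[k] back to loop[1]
  ek <- E[ed[k], ]
  if (!setequal(ek, c(loop[k], loop[1L])))
    stop_tessella("cell %d: edge loop does not close", ci)
  if (anyDuplicated(loop))
    stop_tessella("cell %d: vertex repeated in loop", ci)
  loop
}

signed_area <- function(P) {
  n <- nrow(P)
  j <- c(2:n, 1L)
  0.5 * sum(P[, 1L] * P[j, 2L] - P[j, 1L] * P[, 2L])
}

normalize_winding <- function(t) {
  for (ci in seq_along(t$C)) {
    ## broken cells are skipped here and reported by validate_tissue
    loop <- tryCatch(cell_loop_vertices(t, ci), error = function(e) NULL)
    if (!is.null(loop) &&
        signed_area(t$V[loop, , drop = FALSE]) < 0)
      t$C[[ci]] <- rev(t$C[[ci]])
  }
  t
}

segments_cross <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1; d2 <- q2 - q1
  den <- d1[1L] * d2[2L] - d1[2L] * d2[1L]
  if (abs(den) < 1e-14) return(FALSE)
  s <- ((q1[1L] - p1[1L]) * d2[2L] - (q1[2L] - p1[2L]) * d2[1L]) / den
  u <- ((q1[1L] - p1[1L]) * d1[2L] - (q1[2L] - p1[2L]) * d1[1L]) / den
  eps <- 1e-12
  s > eps && s < 1 - eps && u > eps && u < 1 - eps
}

polygon_simple <- function(P) {
  n <- nrow(P)
  if (n < 4L) return(TRUE)
  nx <- c(2:n, 1L)
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    ## skip adjacent segments (share a vertex)
    if (j == i || nx[i] == j || nx[j] == i) next
    if (segments_cross(P[i, ], P[nx[i], ], P[j, ], P[nx[j], ]))
      return(FALSE)
  }
  TRUE
}

#' Validate a tissue mesh
#'
#' Checks: all edges reference existing vertices, every cell is a closed
#' chain of edges forming a simple polygon of strictly positive area, and
#' every edge belongs to one (boundary) or two cells.  Problems are
#' reported with the offending cell ids.
#'
#' @param t A `tissue`.
#' @return `t`, invisibly; errors on an invalid mesh.
#' @export
validate_tissue <- function(t) {
  nv <- nrow(t$V); ne <- nrow(t$E)
  if (ne && (min(t$E) < 1L || max(t$E) > nv))
    stop_tessella("edge list references missing vertices")
  if (ne && any(t$E[, 1L] == t$E[, 2L]))
    stop_tessella("degenerate edge (identical endpoints)")
  use <- integer(ne)
  bad <- character(0)
  for (ci in seq_along(t$C)) {
    ed <- t$C[[ci]]
    if (any(ed < 1L | ed > ne)) {
      bad <- c(bad, sprintf("cell %d: dangling edge index", ci)); next
    }
    if (anyDuplicated(ed)) {
      bad <- c(bad, sprintf("cell %d: repeated edge", ci)); next
    }
    use[ed] <- use[ed] + 1L
    loop <- tryCatch(cell_loop_vertices(t, ci), error = function(e)
      sprintf("cell %d: %s", ci, conditionMessage(e)))
    if (is.character(loop)) { bad <- c(bad, loop); next }
    P <- t$V[loop, , drop = FALSE]
    a <- signed_area(P)
    if (!(a > 1e-14))
      bad <- c(bad, sprintf("cell %d: non-positive area", ci))
    if (!polygon_simple(P))
      bad <- c(bad, sprintf("cell %d: self-intersecting polygon", ci))
  }
  if (any(use > 2L))
    bad <- c(bad, sprintf("edge(s) %s belong to more than two cells",
                          paste(which(use > 2L), collapse = ",")))
  if (length(bad))
    stop_tessella("invalid tissue:\n  %s", paste(bad, collapse = "\n  "))
  invisible(t)
}

## Topology arrays (combinatorial only; reusable while vertices move) -----
## loop_v[i] -> loop_nx[i] is the directed traversal (CCW) of edge
## loop_edge[i] by cell loop_cell[i].
tissue_topology <- function(t) {
  ncell <- length(t$C)
  loops <- lapply(seq_len(ncell), function(ci) cell_loop_vertices(t, ci))
  len <- lengths(loops)
  loop_cell <- rep.int(seq_len(ncell), len)
  loop_v <- unlist(loops, use.names = FALSE)
  loop_nx <- unlist(lapply(loops, function(l) c(l[-1L], l[1L])),
                    use.names = FALSE)
  loop_edge <- unlist(t$C, use.names = FALSE)
  ne <- nrow(t$E)
  edge_cells <- matrix(NA_integer_, ne, 2L)
  for (i in seq_along(loop_edge)) {
    k <- loop_edge[i]
    if (is.na(edge_cells[k, 1L])) edge_cells[k, 1L] <- loop_cell[i]
    else edge_cells[k, 2L] <- loop_cell[i]
  }
  boundary_edge <- is.na(edge_cells[, 2L])
  adj <- vector("list", ncell)
  int_e <- which(!boundary_edge)
  for (k in int_e) {
    a <- edge_cells[k, 1L]; b <- edge_cells[k, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  list(loops = loops, loop_cell = loop_cell, loop_v = loop_v,
       loop_nx = loop_nx, loop_edge = loop_edge,
       edge_cells = edge_cells, boundary_edge = boundary_edge,
       adjacency = lapply(adj, unique), n_cells = ncell,
       n_edges = ne, n_vertices = nrow(t$V))
}

## Metric quantities at vertex positions V given fixed topology/edges.
## Returns areas, centroids, edge lengths and the outward unit normal of
## each (cell, edge) incidence row; outward normal of a CCW-directed edge
## (dx, dy) is (dy, -dx)/len.
geom_metrics <- function(topo, E, V) {
  ev <- V[topo$loop_v, , drop = FALSE]
  en <- V[topo$loop_nx, , drop = FALSE]
  cross <- ev[, 1L] * en[, 2L] - en[, 1L] * ev[, 2L]
  if (!is.null(topo$S_cell)) {
    area <- 0.5 * as.numeric(topo$S_cell %*% cross)
    cnt <- as.numeric(topo$S_cell %*% rep(1, length(cross)))
    centroid <- as.matrix(topo$S_cell %*% ev) / cnt
  } else {
    area <- 0.5 * add_at(topo$n_cells, topo$loop_cell, cross)
    cnt <- add_at(topo$n_cells, topo$loop_cell,
                  rep(1, length(topo$loop_cell)))
    centroid <- add_at(topo$n_cells, topo$loop_cell, ev) / cnt
  }
  d <- en - ev
  seg_len <- sqrt(d[, 1L]^2 + d[, 2L]^2)
  el <- sqrt(rowSums((V[E[, 1L], , drop = FALSE] -
                      V[E[, 2L], , drop = FALSE])^2))
  list(area = area, centroid = centroid, edge_len = el,
       normals = cbind(d[, 2L], -d[, 1L]) / seg_len)
}

#' Compute the geometry cache of a tissue
#'
#' Shoelace cell areas, arithmetic vertex centroids, edge lengths,
#' edge-to-cell adjacency, and outward unit normals per (cell, edge)
#' incidence.
#'
#' @param t A valid `tissue`.
#' @param V Optional replacement vertex coordinates (same topology), used
#'   during growth when vertices move.
#' @return A list with elements `area` (per cell), `centroid` (cell x 2),
#'   `edge_len` (per edge), `edge_cells` (edge x 2 cell indices, `NA` =
#'   boundary), `boundary_edge` (logical), `adjacency` (list of neighbor
#'   cell indices), `loops` (per-cell ordered vertex indices), and the flat
#'   incidence arrays `loop_cell`, `loop_edge`, `loop_v`, `loop_nx`,
#'   `normals` (outward unit normal per incidence row).
#' @examples
#' sq <- tissue(rbind(c(0,0), c(1,0), c(1,1), c(0,1)),
#'              rbind(c(1,2), c(2,3), c(3,4), c(4,1)),
#'              list(1:4))
#' g <- compute_geometry(sq)
#' g$area       # 1
#' g$centroid   # (0.5, 0.5)
#' @export
compute_geometry <- function(t, V = t$V) {
  topo <- tissue_topology(t)
  m <- geom_metrics(topo, t$E, V)
  if (any(m$edge_len <= 1e-14)) stop_tessella("zero-length edge in tissue")
  if (any(m$area <= 1e-14)) stop_tessella("zero-area cell in tissue")
  c(topo, m)
}

#' Cell polygon coordinates
#'
#' @param t A `tissue`.
#' @param ci Cell index.
#' @param V Optional replacement vertex coordinates.
#' @return A k x 2 matrix of the cell's vertices in counter-clockwise
#'   order.
#' @export
cell_polygon <- function(t, ci, V = t$V) {
  V[cell_loop_vertices(t, ci), , drop = FALSE]
}
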