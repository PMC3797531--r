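## Tissue CSV persistence ------------------------------------------------
##
## Two dialects:
##  * VEC : three CSV tables <prefix>_vertices.csv (id,x,y),
##          <prefix>_edges.csv (id,v1,v2) and <prefix>_cells.csv
##          (id,e1,e2,... ragged rows).
##  * FLAT: one CSV, each row a cell as x1,y1,x2,y2,... in winding order;
##          edges are reconstructed on load with shared edges deduplicated
##          by coordinate identity within tolerance.
## Indices are 1-based internally and 0-based in the files.

## Merge near-coincident points: returns for each row of P the index of
## its representative in the deduplicated set, plus the set itself.
## Bucket grid of size `tol` with 9-neighbourhood lookup, so points that
## straddle a bucket boundary still merge.
dedupe_points <- function(P, tol) {
  n <- nrow(P)
  rep_idx <- integer(n)
  buckets <- new.env(hash = TRUE, parent = emptyenv())
  keep <- integer(0)
  bx <- floor(P[, 1L] / tol); by <- floor(P[, 2L] / tol)
  for (i in seq_len(n)) {
    found <- 0L
    for (dx in -1:1) {
      for (dy in -1:1) {
        key <- paste(bx[i] + dx, by[i] + dy)
        cand <- buckets[[key]]
        if (!is.null(cand)) {
          for (j in cand) {
            if (abs(P[i, 1L] - P[j, 1L]) <= tol &&
                abs(P[i, 2L] - P[j, 2L]) <= tol) { found <- j; break }
          }
        }
        if (found) break
      }
      if (found) break
    }
    if (found) {
      rep_idx[i] <- rep_idx[found]
    } else {
      keep <- c(keep, i)
      rep_idx[i] <- length(keep)
      key <- paste(bx[i], by[i])
      buckets[[key]] <- c(buckets[[key]], i)
    }
  }
  list(map = rep_idx, points = P[keep, , drop = FALSE])
}

#' Assemble a tissue from loose cell polygons
#'
#' Takes one coordinate polygon per cell (vertices in winding order) and
#' reconstructs the shared mesh: vertices coincident within `tol` are
#' merged and edges traversed by two cells are deduplicated, so adjacent
#' polygons end up sharing walls.
#'
#' @param polys List of k x 2 coordinate matrices, one per cell.
#' @param tol Vertex-coincidence tolerance; default 1e-9 times the
#'   bounding-box diagonal.
#' @param validate Validate the assembled mesh.
#' @return A `tissue`.
#' @export
tissue_from_polygons <- function(polys, tol = NULL, validate = TRUE) {
  if (!length(polys)) return(tissue(matrix(0, 0, 2),
                                    matrix(0L, 0, 2), list(),
                                    validate = FALSE))
  allP <- do.call(rbind, polys)
  if (is.null(tol)) {
    rng <- apply(allP, 2L, range)
    tol <- 1e-9 * max(sqrt(sum((rng[2L, ] - rng[1L, ])^2)), 1)
  }
  dd <- dedupe_points(allP, tol)
  V <- dd$points
  sizes <- vapply(polys, nrow, integer(1))
  stop_at <- cumsum(sizes)
  start_at <- c(1L, head(stop_at, -1L) + 1L)
  edge_env <- new.env(hash = TRUE, parent = emptyenv())
  E1 <- integer(0); E2 <- integer(0)
  C <- vector("list", length(polys))
  for (ci in seq_along(polys)) {
    vid <- dd$map[start_at[ci]:stop_at[ci]]
    ## drop consecutive duplicates produced by merging
    k <- length(vid)
    keep <- vid != c(vid[-1L], vid[1L])
    vid <- vid[keep]
    k <- length(vid)
    if (k < 3L) stop_tessella("cell %d degenerates under tolerance", ci)
    nxt <- c(vid[-1L], vid[1L])
    eids <- integer(k)
    for (j in seq_len(k)) {
      a <- min(vid[j], nxt[j]); b <- max(vid[j], nxt[j])
      key <- paste(a, b)
      id <- edge_env[[key]]
      if (is.null(id)) {
        E1 <- c(E1, a); E2 <- c(E2, b)
        id <- length(E1)
        edge_env[[key]] <- id
      }
      eids[j] <- id
    }
    C[[ci]] <- eids
  }
  tissue(V, cbind(E1, E2), C, validate = validate)
}

#' Read a tissue mesh from CSV
#'
#' @param path For the `"flat"` dialect, the CSV file; for `"vec"`, the
#'   path prefix of the three tables `<path>_vertices.csv`,
#'   `<path>_edges.csv`, `<path>_cells.csv`.
#' @param dialect `"vec"` (vertices/edges/cells tables) or `"flat"` (one
#'   row per cell as `x1,y1,x2,y2,...`).
#' @param tol Vertex merge tolerance for FLAT reconstruction (default
#'   1e-9 of the bounding-box diagonal).
#' @return A validated `tissue`.
#' @export
read_tissue <- function(path, dialect = c("vec", "flat"), tol = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "flat") {
    rows <- readLines(path)
    rows <- rows[nzchar(trimws(rows))]
    polys <- lapply(rows, function(r) {
      x <- as.numeric(strsplit(r, ",", fixed = TRUE)[[1L]])
      if (length(x) %% 2L != 0L || anyNA(x))
        stop_tessella("malformed FLAT row: '%s'", r)
      matrix(x, ncol = 2L, byrow = TRUE)
    })
    tissue_from_polygons(polys, tol = tol)
  } else {
    vf <- paste0(path, "_vertices.csv")
    ef <- paste0(path, "_edges.csv")
    cf <- paste0(path, "_cells.csv")
    vt <- utils::read.csv(vf)
    et <- utils::read.csv(ef)
    V <- unname(as.matrix(vt[order(vt$id), c("x", "y")]))
    E <- unname(as.matrix(et[order(et$id), c("v1", "v2")])) + 1L
    rows <- readLines(cf)[-1L]
    rows <- rows[nzchar(trimws(rows))]
    C <- lapply(rows, function(r) {
      x <- as.integer(strsplit(r, ",", fixed = TRUE)[[1L]])
      x[-1L] + 1L
    })
    ids <- vapply(rows, function(r)
      as.integer(strsplit(r, ",", fixed = TRUE)[[1L]][1L]), integer(1))
    tissue(V, E, C[order(ids)])
  }
}

#' Write a tissue mesh to CSV
#'
#' Output is bit-stable for identical input.  The FLAT dialect emits each
#' cell's vertices in counter-clockwise winding order; the VEC dialect
#' writes the three indexed tables with 0-based ids.
#'
#' @param t A `tissue`.
#' @param path Output file (FLAT) or path prefix (VEC).
#' @param dialect `"vec"` or `"flat"`.
#' @return The written file path(s), invisibly.
#' @export
write_tissue <- function(t, path, dialect = c("vec", "flat")) {
  dialect <- match.arg(dialect)
  fmt <- function(x) formatC(x, format = "g", digits = 17)
  if (dialect == "flat") {
    rows <- vapply(seq_along(t$C), function(ci) {
      P <- cell_polygon(t, ci)
      paste(fmt(as.vector(t(P))), collapse = ",")
    }, character(1))
    writeLines(rows, path)
    invisible(path)
  } else {
    vf <- paste0(path, "_vertices.csv")
    ef <- paste0(path, "_edges.csv")
    cf <- paste0(path, "_cells.csv")
    writeLines(c("id,x,y",
                 sprintf("%d,%s,%s", seq_len(nrow(t$V)) - 1L,
                         fmt(t$V[, 1L]), fmt(t$V[, 2L]))), vf)
    writeLines(c("id,v1,v2",
                 if (nrow(t$E)) sprintf("%d,%d,%d",
                                        seq_len(nrow(t$E)) - 1L,
                                        t$E[, 1L] - 1L, t$E[, 2L] - 1L)),
               ef)
    writeLines(c("id,edges",
                 vapply(seq_along(t$C), function(ci)
                   paste(c(ci - 1L, t$C[[ci]] - 1L), collapse = ","),
                   character(1))), cf)
    invisible(c(vf, ef, cf))
  }
}
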