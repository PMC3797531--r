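## Intercellular arrows --------------------------------------------------
##
## Diffusion, facilitated transport and action-at-a-distance (IGRN) over
## the tissue topology.  Fick diffusion of X across the wall k between
## cells i and j contributes
##     d[X_i]/dt += (l_k / A_i) * beta(i,j,k) * ([X_j] - [X_i])
## and the mirrored term to j; boundary walls exchange with a
## zero-concentration exterior at permeability P_O (omitted P_O = closed
## boundary).  Permeabilities and fluxes may be numbers or functions
## `f(i, j, k, C)` of (cell, neighbour, wall) vectors plus the current
## concentration matrix, evaluated per wall at every RHS call.

new_ic_arrow <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "intercellular_arrow")
}

#' Intercellular arrow constructors
#'
#' * `diffusion_arrow(species, PI, PO)` — Fickian diffusion with interior
#'   wall permeability `PI` and optional boundary permeability `PO`
#'   (omitted = impermeable tissue boundary; the exterior concentration is
#'   zero).
#' * `transport_arrow(species, f_out, f_in)` — facilitated transport with
#'   positive directed wall fluxes; supply at least one of the two.
#' * `igrn_arrow(from, to, v, T, n, h)` — intercellular GRN: `X` in a cell
#'   drives `Y` in each adjacent cell through a saturating logistic
#'   response \eqn{v/(1 + e^{-h - T [X]^n})}; contributions from several
#'   neighbours add.
#'
#' @param species,from,to Species names.
#' @param PI,PO Permeabilities: numbers or `f(i, j, k, C)` (vectorised
#'   over walls).
#' @param f_out,f_in Directed wall fluxes, numbers or `f(i, j, k, C)`;
#'   must evaluate non-negative.
#' @param v,T,n,h IGRN response parameters.
#' @return An `intercellular_arrow`.
#' @export
diffusion_arrow <- function(species, PI, PO = NULL)
  new_ic_arrow("diffusion", species = species, PI = PI, PO = PO)

#' @rdname diffusion_arrow
#' @export
transport_arrow <- function(species, f_out = NULL, f_in = NULL) {
  if (is.null(f_out) && is.null(f_in))
    stop_tessella("transport arrow needs at least one of f_out, f_in")
  new_ic_arrow("transport", species = species,
               f_out = f_out %||% 0, f_in = f_in %||% 0)
}

#' @rdname diffusion_arrow
#' @export
igrn_arrow <- function(from, to, v, T, n = 1, h = 0)
  new_ic_arrow("igrn", from = from, to = to, v = v, T = T, n = n, h = h)

## evaluate a wall quantity: constant or f(i, j, k, C)
wall_val <- function(p, i, j, k, C) {
  if (is.function(p)) p(i, j, k, C) else rep_len(p, length(i))
}

ic_resolve <- function(p, parameters)
  if (is.character(p)) resolve_param(p, parameters) else p

#' Expand a diffusion arrow over a tissue
#'
#' @param arrow A [diffusion_arrow()].
#' @param t A `tissue`.
#' @param g Its geometry from [compute_geometry()].
#' @param parameters Named list resolving symbolic permeabilities.
#' @return An `ode_terms` object with the per-cell diffusion fluxes for
#'   the arrow's species.  During growth the terms read current geometry
#'   from `ctx$geom`.
#' @examples
#' t2 <- hex_template(1)
#' g2 <- compute_geometry(t2)
#' dt <- expand_diffusion(diffusion_arrow("X", PI = 1), t2, g2)
#' @export
expand_diffusion <- function(arrow, t, g, parameters = list()) {
  stopifnot(arrow$kind == "diffusion")
  sp <- arrow$species
  PI <- ic_resolve(arrow$PI, parameters)
  PO <- if (!is.null(arrow$PO)) ic_resolve(arrow$PO, parameters)
  int_k <- which(!g$boundary_edge)
  bnd_k <- which(g$boundary_edge)
  ii <- g$edge_cells[int_k, 1L]; jj <- g$edge_cells[int_k, 2L]
  bi <- g$edge_cells[bnd_k, 1L]
  nc <- g$n_cells
  const_beta <- !is.function(PI) && (is.null(PO) || !is.function(PO))
  ## signed wall->cell incidence for the growing-geometry path:
  ## dX = (S_w %*% q)/area with q the per-wall flux l*beta*(X_j - X_i)
  S_w <- if (length(int_k))
    Matrix::sparseMatrix(i = c(ii, jj),
                         j = c(seq_along(int_k), seq_along(int_k)),
                         x = c(rep(1, length(int_k)),
                               rep(-1, length(int_k))),
                         dims = c(nc, length(int_k)))
  S_b <- if (length(bnd_k))
    Matrix::sparseMatrix(i = bi, j = seq_along(bnd_k),
                         x = rep(1, length(bnd_k)),
                         dims = c(nc, length(bnd_k)))
  build_L <- function(G) {
    ## weighted diffusion operator in concentration basis: dX = L X
    l <- G$edge_len[int_k]
    wi <- (l / G$area[ii]) * PI
    wj <- (l / G$area[jj]) * PI
    i_idx <- c(ii, ii, jj, jj); j_idx <- c(jj, ii, ii, jj)
    x <- c(wi, -wi, wj, -wj)
    if (!is.null(PO) && length(bnd_k)) {
      wb <- (G$edge_len[bnd_k] / G$area[bi]) * PO
      i_idx <- c(i_idx, bi); j_idx <- c(j_idx, bi); x <- c(x, -wb)
    }
    Matrix::sparseMatrix(i = i_idx, j = j_idx, x = x, dims = c(nc, nc))
  }
  L0 <- if (const_beta) build_L(g)
  fn <- function(C, t_, ctx) {
    G <- ctx$geom
    X <- C[, sp]
    if (const_beta && is.null(G)) return(as.numeric(L0 %*% X))
    G <- G %||% g
    beta <- if (const_beta) PI else wall_val(PI, ii, jj, int_k, C)
    out <- numeric(nc)
    if (length(int_k)) {
      q <- G$edge_len[int_k] * beta * (X[jj] - X[ii])
      out <- as.numeric(S_w %*% q) / G$area
    }
    if (!is.null(PO) && length(bnd_k)) {
      bb <- if (const_beta) PO
            else wall_val(PO, bi, rep(NA_integer_, length(bi)), bnd_k, C)
      out <- out -
        as.numeric(S_b %*% (G$edge_len[bnd_k] * bb * X[bi])) / G$area
    }
    out
  }
  new_ode_terms(list(list(species = sp, fn = fn)))
}

#' Expand a transport arrow over a tissue
#'
#' Implements the paired source/sink wall fluxes: for each interior wall
#' k between cells i and j,
#' \eqn{d[X_i]/dt = (l_k/A_i)(f_{in}(i,j,k) - f_{out}(i,j,k) -
#' f_{in}(j,i,k) + f_{out}(j,i,k))}, and the mirrored term for j.
#' Fluxes are defined positive; a callable returning a negative value is
#' an error.
#'
#' @inheritParams expand_diffusion
#' @param arrow A [transport_arrow()].
#' @return An `ode_terms` object.
#' @export
expand_transport <- function(arrow, t, g, parameters = list()) {
  stopifnot(arrow$kind == "transport")
  sp <- arrow$species
  fo <- ic_resolve(arrow$f_out, parameters)
  fi <- ic_resolve(arrow$f_in, parameters)
  int_k <- which(!g$boundary_edge)
  ii <- g$edge_cells[int_k, 1L]; jj <- g$edge_cells[int_k, 2L]
  nc <- g$n_cells
  fn <- function(C, t_, ctx) {
    G <- ctx$geom %||% g
    fin_ij <- wall_val(fi, ii, jj, int_k, C)
    fin_ji <- wall_val(fi, jj, ii, int_k, C)
    fout_ij <- wall_val(fo, ii, jj, int_k, C)
    fout_ji <- wall_val(fo, jj, ii, int_k, C)
    if (any(c(fin_ij, fin_ji, fout_ij, fout_ji) < 0))
      stop_tessella("transport fluxes must be non-negative")
    l <- G$edge_len[int_k]
    net <- fin_ij - fout_ij - fin_ji + fout_ji
    add_at(nc, c(ii, jj), c(l / G$area[ii] * net, -l / G$area[jj] * net))
  }
  new_ode_terms(list(list(species = sp, fn = fn)))
}

#' Expand an intercellular GRN arrow over a tissue
#'
#' For each ordered adjacent cell pair (i, j), species `from` in cell i
#' adds \eqn{v/(1 + e^{-h - T [X_i]^n})} to the rate of species `to` in
#' cell j; contributions from multiple neighbours accumulate.
#'
#' @inheritParams expand_diffusion
#' @param arrow An [igrn_arrow()].
#' @return An `ode_terms` object.
#' @export
expand_igrn <- function(arrow, t, g, parameters = list()) {
  stopifnot(arrow$kind == "igrn")
  from <- arrow$from; to <- arrow$to
  v <- ic_resolve(arrow$v, parameters)
  Tw <- ic_resolve(arrow$T, parameters)
  n <- ic_resolve(arrow$n, parameters)
  h <- ic_resolve(arrow$h, parameters)
  int_k <- which(!g$boundary_edge)
  a <- g$edge_cells[int_k, 1L]; b <- g$edge_cells[int_k, 2L]
  src <- c(a, b); dst <- c(b, a)
  nc <- g$n_cells
  fn <- function(C, t_, ctx) {
    z <- v * ctrl_logistic(h + Tw * C[src, from]^n)
    add_at(nc, dst, z)
  }
  new_ode_terms(list(list(species = to, fn = fn)))
}

#' @keywords internal
expand_intercellular <- function(arrow, t, g, parameters = list()) {
  switch(arrow$kind,
         diffusion = expand_diffusion(arrow, t, g, parameters),
         transport = expand_transport(arrow, t, g, parameters),
         igrn = expand_igrn(arrow, t, g, parameters),
         stop_tessella("unknown intercellular arrow '%s'", arrow$kind))
}
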