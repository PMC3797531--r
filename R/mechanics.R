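## Tissue mechanics -------------------------------------------------------
##
## Overdamped spring-pressure vertex dynamics.  Each wall is a Hookean
## spring with rest length delta_r and constant k_r; each cell pushes its
## walls outward with pressure P_a.  Vertex velocity (velocity ~ force):
##
##   dx_i/dt = sum_r k_r (x_j - x_i)(1 - delta_r / l_r)
##           + sum_(r,a) 1/2 P_a l_r n_{a,r}
##
## (first sum over edges r = (i,j) incident on i, second over incidences
## of owning cells a; the wall's pressure force P l n is split half to
## each endpoint).  Rest lengths grow irreversibly under tension:
## d delta_r/dt = mu_r * max(l_r - delta_r, 0).

#' Mechanical state of a tissue
#'
#' @param t A `tissue`.
#' @param g Its geometry (default computed).
#' @param delta Per-edge rest lengths; default = current edge lengths
#'   (tissue born at mechanical rest).
#' @param k Spring constant: number, per-edge vector, or function
#'   `f(p, q, r, C)` of the abutting cells p, q (q `NA` on the boundary)
#'   and wall index r, vectorised over walls.
#' @param P Cell pressure: number, per-cell vector, or function
#'   `f(ctx)` returning a per-cell vector (ctx carries `C`, `geom`,
#'   `indicators`).
#' @param mu Rest-length growth coefficient: number, per-edge vector, or
#'   `f(p, q, r, C)` like `k`.
#' @return A `mech_state` object.
#' @export
mech_state <- function(t, g = compute_geometry(t), delta = NULL,
                       k = 1, P = 0, mu = 0) {
  delta <- delta %||% g$edge_len
  if (any(delta <= 0)) stop_tessella("rest lengths must be positive")
  structure(list(delta = delta, k = k, P = P, mu = mu),
            class = "mech_state")
}

## per-edge value from number/vector/function(p, q, r, C)
edge_val <- function(p, g, C) {
  if (is.function(p))
    p(g$edge_cells[, 1L], g$edge_cells[, 2L], seq_len(g$n_edges), C)
  else rep_len(p, g$n_edges)
}

## per-cell value from number/vector/function(ctx)
cell_val <- function(p, g, C, t = 0, ctx = NULL) {
  if (is.function(p)) p(make_ctx(C, t, ctx)) else rep_len(p, g$n_cells)
}

#' Vertex velocities under spring and pressure forces
#'
#' @param t A `tissue`.
#' @param g Geometry at the current vertex positions.
#' @param m A [mech_state()].
#' @param C Optional concentration matrix for constituent-dependent
#'   spring constants / pressures.
#' @param ctx Optional evaluation context (indicators etc.).
#' @return An n_vertices x 2 matrix of velocities.
#' @export
vertex_velocities <- function(t, g, m, C = NULL, ctx = NULL) {
  if (any(g$edge_len <= 1e-14))
    stop_tessella("singular geometry: zero-length edge")
  nv <- nrow(t$V)
  V <- if (!is.null(ctx) && !is.null(ctx$V)) ctx$V else t$V
  i <- t$E[, 1L]; j <- t$E[, 2L]
  kr <- edge_val(m$k, g, C)
  if (any(kr < 0)) stop_tessella("negative spring constant")
  d <- V[j, , drop = FALSE] - V[i, , drop = FALSE]
  f <- kr * (1 - m$delta / g$edge_len)
  vel <- if (!is.null(g$S_spring))
    as.matrix(g$S_spring %*% (f * d))
  else add_at(nv, c(i, j), rbind(f * d, -f * d))
  Pa <- cell_val(m$P, g, C, ctx = ctx)
  if (any(Pa < 0)) stop_tessella("negative pressure")
  if (any(Pa > 0)) {
    w <- 0.5 * Pa[g$loop_cell] * g$edge_len[g$loop_edge] * g$normals
    vel <- vel + if (!is.null(g$S_press))
      as.matrix(g$S_press %*% w)
    else add_at(nv, c(g$loop_v, g$loop_nx), rbind(w, w))
  }
  vel
}

## Cache sparse accumulation patterns on a geometry object: fixed while
## the topology is fixed, so the growing-mode RHS avoids rowsum calls.
geom_with_accumulators <- function(t, g) {
  nv <- nrow(t$V)
  ne <- nrow(t$E)
  L <- length(g$loop_cell)
  g$S_spring <- Matrix::sparseMatrix(
    i = c(t$E[, 1L], t$E[, 2L]), j = c(seq_len(ne), seq_len(ne)),
    x = c(rep(1, ne), rep(-1, ne)), dims = c(nv, ne))
  g$S_press <- Matrix::sparseMatrix(
    i = c(g$loop_v, g$loop_nx), j = c(seq_len(L), seq_len(L)),
    x = rep(1, 2L * L), dims = c(nv, L))
  g$S_cell <- Matrix::sparseMatrix(
    i = g$loop_cell, j = seq_len(L), x = rep(1, L),
    dims = c(g$n_cells, L))
  g
}

#' Ramp function \eqn{\Theta(x) = (x + |x|)/2}
#'
#' The positive part: rest lengths grow only while the spring is extended.
#' @param x Numeric vector.
#' @return `pmax(x, 0)`.
#' @export
theta_ramp <- function(x) (x + abs(x)) / 2

#' Rest-length growth rates
#'
#' \eqn{d\delta_r/dt = \mu_r \Theta(\ell_r - \delta_r)}: proportional to
#' the extension beyond rest; compressed or resting springs do not grow.
#'
#' @param m A [mech_state()].
#' @param g Geometry at current vertex positions.
#' @param C Optional concentrations for constituent-dependent `mu`.
#' @return Per-edge d(delta)/dt vector.
#' @export
rest_length_rates <- function(m, g, C = NULL) {
  mu <- edge_val(m$mu, g, C)
  mu * theta_ramp(g$edge_len - m$delta)
}

#' Cell area growth rates from vertex velocities
#'
#' Time derivative of the shoelace area under the given vertex velocity
#' field.
#'
#' @param t A `tissue`.
#' @param g Its geometry.
#' @param velocities n_vertices x 2 velocity matrix.
#' @param V Optional current vertex positions (default `t$V`).
#' @return Per-cell dA/dt vector.
#' @export
cell_area_rate <- function(t, g, velocities, V = t$V) {
  xv <- V[g$loop_v, , drop = FALSE]; xn <- V[g$loop_nx, , drop = FALSE]
  vv <- velocities[g$loop_v, , drop = FALSE]
  vn <- velocities[g$loop_nx, , drop = FALSE]
  dcross <- vv[, 1L] * xn[, 2L] + xv[, 1L] * vn[, 2L] -
    vn[, 1L] * xv[, 2L] - xn[, 1L] * vv[, 2L]
  if (!is.null(g$S_cell)) 0.5 * as.numeric(g$S_cell %*% dcross)
  else 0.5 * add_at(g$n_cells, g$loop_cell, dcross)
}

#' Dilution terms for growing cells
#'
#' Concentration is amount over volume, so growth at fixed molecule count
#' dilutes: each species in each cell receives
#' \eqn{-[X_i] (dA_i/dt) / A_i}.
#'
#' @param species Character vector of (non-fixed) species to dilute.
#' @param t A `tissue`.
#' @param g Its geometry.
#' @param velocities Vertex velocity matrix, as from
#'   [vertex_velocities()].
#' @return An `ode_terms` object.  When evaluated with a context carrying
#'   `geom`, `V` and `velocities`, current values are used (growing runs);
#'   otherwise the captured ones.
#' @export
dilution_terms <- function(species, t, g, velocities = NULL) {
  terms <- lapply(species, function(sp) {
    list(species = sp, fn = function(C, t_, ctx) {
      G <- ctx$geom %||% g
      vel <- ctx$velocities %||% velocities
      V <- ctx$V %||% t$V
      if (is.null(vel)) return(numeric(G$n_cells))
      dA <- cell_area_rate(t, G, vel, V = V)
      -C[, sp] * dA / G$area
    })
  })
  new_ode_terms(terms)
}

#' Closed-form growth of a single square cell
#'
#' For one square cell with uniform spring constant `k`, pressure `P`,
#' total rest length `Delta` and no rest-length growth (`mu = 0`), the
#' vertex dynamics reduce to a single ODE for the perimeter L:
#' \deqn{\frac{1}{L}\frac{dL}{dt} = P - 2k + \frac{2k\Delta}{L}.}
#' For `P < 2k` the perimeter approaches the finite equilibrium
#' \eqn{L^* = 2k\Delta/(2k - P)} sigmoidally; for `P >= 2k` growth is
#' unbounded.  Used as the analytic oracle for the mechanics integrator.
#'
#' @param k Spring constant.
#' @param P Cell pressure.
#' @param Delta Total rest length (sum of the four sides').
#' @return A list: `rate(L)` (the relative growth rate function `dL/dt/L`),
#'   `L_star` (equilibrium perimeter, `Inf` when unbounded),
#'   `bounded` (`P < 2k`).
#' @examples
#' square_cell_closed_form(k = 1, P = 1, Delta = 4)$L_star   # 8
#' @export
square_cell_closed_form <- function(k, P, Delta) {
  list(rate = function(L) P - 2 * k + 2 * k * Delta / L,
       L_star = if (P < 2 * k) 2 * k * Delta / (2 * k - P) else Inf,
       bounded = P < 2 * k)
}

#' Growth (Grow arrow) specification
#'
#' Mirrors the model-level Grow arrow: how pressure, rest-length growth
#' rate and spring constant depend on cell constituents.  Each component
#' is either a constant or a feedback function (see [mech_state()] for
#' the callable signatures); the common affine case
#' \eqn{P_i = p_0 + p_1 W_i} is written
#' `grow_arrow(pressure = pressure_feedback("W", 0.001, 0.004), ...)`.
#'
#' @param pressure Number, per-cell vector, or `f(ctx)`.
#' @param growth_rate Number, per-edge vector, or `f(p, q, r, C)`.
#' @param spring Number, per-edge vector, or `f(p, q, r, C)`.
#' @return A `grow_arrow` object.
#' @export
grow_arrow <- function(pressure = 0, growth_rate = 0, spring = 1) {
  structure(list(pressure = pressure, growth_rate = growth_rate,
                 spring = spring),
            class = "grow_arrow")
}

#' @rdname grow_arrow
#' @param species Species name feeding back on the parameter.
#' @param base,slope Affine feedback coefficients.
#' @export
pressure_feedback <- function(species, base, slope) {
  force(species); force(base); force(slope)
  function(ctx) base + slope * ctx$C[, species]
}

#' @rdname grow_arrow
#' @details `growth_feedback()` implements
#'   \eqn{\mu_r = \mu_0 + \mu_1 (W_p + W_q)} over the cells p, q abutting
#'   each wall (a boundary wall uses its single cell's value twice).
#' @export
growth_feedback <- function(species, base, slope) {
  force(species); force(base); force(slope)
  function(p, q, r, C) {
    wq <- ifelse(is.na(q), C[p, species], C[q, species])
    base + slope * (C[p, species] + wq)
  }
}
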