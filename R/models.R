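## Demonstration models ---------------------------------------------------

#' Classify tissue layers (L1 / L2 / TIP)
#'
#' Location indicators used by the meristem models: `L1` marks epidermal
#' cells (owning at least one boundary edge), `L2` the subepidermal layer
#' (adjacent to an L1 cell, not itself L1), and `TIP` the apex cells
#' (centroid within the top `tip_frac` of the tissue bounding-box
#' height).  A pure function of topology and geometry; the growing-mode
#' engine re-evaluates it after every division.
#'
#' @param t A `tissue`.
#' @param g Its geometry (computed if missing).
#' @param tip_frac Apex region as a fraction of bounding-box height.
#' @return A list of numeric 0/1 vectors `L1`, `L2`, `TIP`.
#' @export
classify_layers <- function(t, g = compute_geometry(t), tip_frac = 0.1) {
  nc <- g$n_cells
  L1 <- logical(nc)
  bcells <- g$edge_cells[g$boundary_edge, 1L]
  L1[bcells] <- TRUE
  L2 <- vapply(seq_len(nc), function(i)
    !L1[i] && any(L1[g$adjacency[[i]]]), logical(1))
  ytop <- max(t$V[, 2L]); ybot <- min(t$V[, 2L])
  TIP <- g$centroid[, 2L] >= ytop - tip_frac * (ytop - ybot)
  list(L1 = as.numeric(L1), L2 = as.numeric(L2), TIP = as.numeric(TIP))
}

#' Summarise a spatial expression pattern
#'
#' @param field Per-cell values (length = cell count).
#' @param t A `tissue`.
#' @param high_threshold Threshold defining "high-expression" cells.
#' @param g Geometry (computed if missing).
#' @return A list: `n_maxima` and `maxima` (cells strictly exceeding all
#'   adjacent cells), `n_domains` and `domains` (connected components of
#'   the high-expression cell set in the adjacency graph).
#' @export
pattern_summary <- function(field, t, high_threshold = NULL,
                            g = compute_geometry(t)) {
  nc <- g$n_cells
  stopifnot(length(field) == nc)
  maxima <- which(vapply(seq_len(nc), function(i) {
    nb <- g$adjacency[[i]]
    length(nb) > 0L && all(field[i] > field[nb])
  }, logical(1)))
  domains <- list()
  if (!is.null(high_threshold)) {
    high <- field >= high_threshold
    seen <- logical(nc)
    for (i in which(high)) {
      if (seen[i]) next
      comp <- integer(0); queue <- i; seen[i] <- TRUE
      while (length(queue)) {
        v <- queue[[1L]]; queue <- queue[-1L]
        comp <- c(comp, v)
        for (w in g$adjacency[[v]])
          if (high[w] && !seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
      domains[[length(domains) + 1L]] <- sort(comp)
    }
  }
  list(n_maxima = length(maxima), maxima = maxima,
       n_domains = length(domains), domains = domains)
}

#' Diffusible Brusselator model
#'
#' The reaction set `0 <-> A` (rates a, beta), `2A + B -> 3A` (c),
#' `A -> B` (b), with both species diffusing at permeabilities `D_A`,
#' `D_B` (applied to interior and boundary walls alike).  The well-mixed
#' fixed point is \eqn{A^* = a/\beta}, \eqn{B^* = b\beta/(ca)}; for
#' \eqn{b > \beta + ca^2/\beta^2 \cdot ...} (here b > 0.2 at the default
#' a = beta = c = 0.1) the single-cell system oscillates on a limit
#' cycle, and with \eqn{D_A \ll D_B} the coupled tissue freezes into a
#' stationary heterogeneous pattern.
#'
#' @param a,beta,b,c Kinetic parameters (defaults a = beta = c = 0.1; b
#'   has no published default and must be chosen — 0.25 places the
#'   well-mixed system in its oscillatory regime).
#' @param D_A,D_B Wall permeabilities of A and B.
#' @param perturb Relative amplitude of the random per-cell perturbation
#'   of the initial state around the fixed point (0 = exactly uniform;
#'   draws use the caller's RNG stream).
#' @param open_boundary Apply the permeabilities to the tissue boundary
#'   walls as well (the canonical form).  Set `FALSE` for a closed
#'   tissue, e.g. to make all cells dynamically equivalent — with an
#'   open boundary, boundary cells drain and differ from interior ones
#'   even at equal diffusivities.
#' @return A [model_spec()].
#' @export
brusselator_model <- function(a = 0.1, beta = 0.1, b = 0.25, c = 0.1,
                              D_A = 0, D_B = 0.5, perturb = 0.5,
                              open_boundary = TRUE) {
  A_star <- a / beta
  B_star <- b * beta / (c * a)
  init_fn <- function(star) {
    force(star)
    function(t, g) star * (1 + perturb * stats::runif(g$n_cells, -1, 1))
  }
  model_spec(
    reactions = c(parse_arrow("0 <-> A", list(a, beta)),
                  parse_arrow("2A + B -> 3A", c),
                  parse_arrow("A -> B", b)),
    intercellular = list(
      diffusion_arrow("A", PI = D_A, PO = if (open_boundary) D_A),
      diffusion_arrow("B", PI = D_B, PO = if (open_boundary) D_B)),
    species = list(A = list(init = init_fn(A_star)),
                   B = list(init = init_fn(B_star))),
    parameters = list(a = a, beta = beta, b = b, c = c))
}

#' WUS/CLV stem-cell niche model
#'
#' A Brusselator provides the positioning signal A; the boundary cells
#' (standing in for the omitted L1 layer) hold the signal protein Y fixed
#' at `y_boundary`, from where it diffuses inward and decays.  WUS (`W`)
#' is activated through a saturating GRN response to (Y, A) with the
#' sigma control function; Y also degrades A (`A + Y -> Y`).
#'
#' @param v,T_WY,T_WA,h,k_w,k_y,d,D_Y WUS-network parameters (defaults
#'   from the published simulation: v = 0.1, T_WY = -25, T_WA = 0.5,
#'   h = 0, k_w = 0.1, k_y = 0.1, d = 0.5, D_Y = 2).
#' @param D_A,D_B Brusselator permeabilities (published: 1.5 and 15).
#' @param a,beta,b,c Brusselator kinetics (see [brusselator_model()]).
#' @param y_boundary Fixed Y concentration in boundary cells (not
#'   published; default 1).
#' @param perturb Initial perturbation amplitude, as in
#'   [brusselator_model()].
#' @param fixed_cells Cells holding Y fixed: `NULL` (all cells owning a
#'   boundary edge) or an explicit index vector.  For ablation
#'   experiments pass the *original* tissue's boundary cells so that the
#'   wound edge does not become a Y source.
#' @return A [model_spec()].
#' @export
wus_model <- function(v = 0.1, T_WY = -25, T_WA = 0.5, h = 0,
                      k_w = 0.1, k_y = 0.1, d = 0.5, D_Y = 2,
                      D_A = 1.5, D_B = 15, a = 0.1, beta = 0.1,
                      b = 0.25, c = 0.1, y_boundary = 1,
                      perturb = 0.5, fixed_cells = NULL) {
  bru <- brusselator_model(a, beta, b, c, D_A, D_B, perturb)
  boundary_cells <- function(t, g) {
    out <- logical(g$n_cells)
    if (is.null(fixed_cells))
      out[g$edge_cells[g$boundary_edge, 1L]] <- TRUE
    else out[fixed_cells] <- TRUE
    if (!any(out))
      stop_tessella("wus_model: tissue has no boundary cells")
    out
  }
  model_spec(
    reactions = c(bru$reactions,
                  list(reaction("Y + A -> W",
                                grn(v = v, T = c(T_WY, T_WA), n = 1,
                                    h = h, control = "sigma")),
                       reaction("W -> 0", k_w),
                       reaction("Y -> 0", k_y),
                       reaction("A + Y -> Y", d))),
    intercellular = c(bru$intercellular,
                      list(diffusion_arrow("Y", PI = D_Y, PO = D_Y))),
    species = c(bru$species,
                list(Y = list(init = function(t, g)
                       y_boundary * boundary_cells(t, g),
                     fixed = boundary_cells),
                     W = list(init = 0))),
    parameters = list(v = v, T_WY = T_WY, T_WA = T_WA, h = h,
                      k_w = k_w, k_y = k_y, d = d, D_Y = D_Y))
}

#' Organizer-maintained growth model
#'
#' A simplified stem-cell-niche maintenance network on a growing,
#' dividing tissue.  `U` (cytokinin-like) is produced only in the apex
#' (`TIP`), `V` (CLV-like) only in the epidermis (`L1`); both diffuse
#' through interior walls (the epidermis is impermeable: no boundary
#' permeability).  The organizer species `W` is activated by U,
#' repressed by V and self-activating through a GRN response; its
#' constitutive degradation (via the readout `Z`, which U suppresses) is
#' enhanced in the subepidermal `L2` layer.  `X` diffuses W's positive
#' feedback onto V.  Pressure and wall growth feed back on W:
#' \eqn{P_i = p_0 + p_1 W_i}, \eqn{\mu_r = \mu_0 + \mu_1 (W_p + W_q)};
#' division follows Errera's rule.
#'
#' @param k1,k2,k3,k4,k5,k6,k8,k9 Production/decay rates (published
#'   values are the defaults).
#' @param k7 Base production of Z (not published; must be chosen: it
#'   sets the W plateau \eqn{W \approx v_W k_8 U/(k_6 k_7)} where the
#'   GRN response is switched on).  The default 200 puts niche W at
#'   order 1, keeping the pressure contrast between niche and bulk
#'   mechanically safe: much larger W (small k7) lets the growing niche
#'   fold its W-free neighbours (polygon inversion).
#' @param D_U,D_V,D_X Interior wall permeabilities.
#' @param v_V,v_W,v_X,h_V,h_W,h_X,T_WX,T_WV,T_UW,T_VW,T_WW GRN response
#'   parameters.
#' @param p0,p1,mu0,mu1 Mechanical feedback coefficients.
#' @param spring Spring law: `NULL` (default) uses the W-gated wall
#'   stiffness \eqn{k_r = k_{soft} + (k_{rigid} - k_{soft})/(1 +
#'   \min(W_p, W_q)^2)} — walls inside the W-expressing niche (and its
#'   free surface) are soft and extensible, every wall touching a W-free
#'   differentiated cell is stiff.
#'   Nothing is published for the spring constant; a single soft value
#'   for every wall lets the growing niche mechanically crush its W-free
#'   neighbours (polygon inversion), while a single stiff value stalls
#'   growth, so differential stiffness is the package's choice of the
#'   model's `f_k` feedback.  A number or `f(p, q, r, C)` overrides.
#' @param div_mean,div_sd Division threshold distribution (area).
#' @param tip_frac Apex indicator region (fraction of bounding-box
#'   height).
#' @param init Named list of initial concentrations (default all 0: at
#'   the default k7 the apex U level switches the W response on
#'   directly, so no preset W field is needed).
#' @return A [model_spec()] in growing mode.
#' @export
organizer_growth_model <- function(k1 = 2, k2 = 0.2, k3 = 1, k4 = 0.25,
                                   k5 = 1, k6 = 0.05, k8 = 1.5,
                                   k9 = 0.1, D_U = 10, D_V = 0.5,
                                   D_X = 0.5, v_X = 1, v_W = 1, v_V = 1,
                                   h_X = 0, h_W = 0, h_V = 0, T_WX = 4,
                                   T_WV = 4, T_UW = 22.5, T_VW = -25,
                                   T_WW = 27.5, p0 = 0.001, p1 = 0.004,
                                   mu0 = 5e-6, mu1 = 0.004, spring = 0.002,
                                   k7 = 200, div_mean = 2, div_sd = 0.1,
                                   tip_frac = 0.5, init = list()) {
  tip_rate <- function(ctx) k1 * ctx$ind$TIP
  l1_rate <- function(ctx) k3 * ctx$ind$L1
  w_decay <- function(ctx) k6 * ctx$C[, "Z"] + k9 * ctx$ind$L2
  z_decay <- function(ctx) k8 * ctx$C[, "U"]
  sp <- list(U = list(init = init$U %||% 0),
             V = list(init = init$V %||% 0),
             W = list(init = init$W %||% 0),
             X = list(init = init$X %||% 0),
             Z = list(init = init$Z %||% 0))
  model_spec(
    reactions = c(
      parse_arrow("0 -> U", mass_action(tip_rate)),
      parse_arrow("U -> 0", k2),
      parse_arrow("0 -> V", mass_action(l1_rate)),
      parse_arrow("V -> 0", k4),
      parse_arrow("0 <-> Z", list(k7, mass_action(z_decay))),
      list(reaction("X -> V", grn(v = v_V, T = T_WV, n = 1, h = h_V)),
           reaction("U + V + W -> W",
                    grn(v = v_W, T = c(T_UW, T_VW, T_WW), n = 1,
                        h = h_W)),
           reaction("W -> X", grn(v = v_X, T = T_WX, n = 1, h = h_X))),
      parse_arrow("W -> 0", mass_action(w_decay)),
      parse_arrow("X -> 0", k5)),
    intercellular = list(diffusion_arrow("U", PI = D_U),
                         diffusion_arrow("V", PI = D_V),
                         diffusion_arrow("X", PI = D_X)),
    species = sp,
    parameters = list(),
    grow = grow_arrow(pressure = pressure_feedback("W", p0, p1),
                      growth_rate = growth_feedback("W", mu0, mu1),
                      spring = spring),
    divide = division_spec("errera", variable = "area",
                           mean = div_mean, sd = div_sd),
    indicators = function(t, g) classify_layers(t, g, tip_frac))
}

#' Remove cells from a tissue (ablation)
#'
#' Deletes the given cells and prunes edges and vertices that no
#' remaining cell uses; models laser-ablation experiments when applied
#' before compilation.
#'
#' @param t A `tissue`.
#' @param cells Cell indices to remove.
#' @return The reduced `tissue`.
#' @export
ablate_cells <- function(t, cells) {
  keepC <- setdiff(seq_along(t$C), cells)
  if (!length(keepC)) stop_tessella("ablation would remove every cell")
  usedE <- sort(unique(unlist(t$C[keepC])))
  emap <- integer(nrow(t$E)); emap[usedE] <- seq_along(usedE)
  E <- t$E[usedE, , drop = FALSE]
  usedV <- sort(unique(as.vector(E)))
  vmap <- integer(nrow(t$V)); vmap[usedV] <- seq_along(usedV)
  E <- matrix(vmap[E], ncol = 2L)
  C <- lapply(t$C[keepC], function(ed) emap[ed])
  tissue(t$V[usedV, , drop = FALSE], E, C)
}

#' Meristem-dome tissue template
#'
#' A half-hexagonal-disk "dome": a centred hexagonal array with the cells
#' below the midline removed.  The flat bottom and the arc are both
#' tissue boundary; the apex (TIP) sits at the top.  This is the packaged
#' fixture geometry for the stem-cell-niche demonstrations (mirror
#' symmetric, so paired expression domains land symmetrically).
#'
#' @param rings Hex array rings before halving.
#' @param side Cell side length.
#' @return A `tissue`.
#' @export
dome_template <- function(rings = 5, side = 3) {
  h <- hex_template(rings, side)
  g <- compute_geometry(h)
  ablate_cells(h, which(g$centroid[, 2L] < -0.1 * side))
}

#' Cells nearest the tissue center
#'
#' @param t A `tissue`.
#' @param n How many cells.
#' @param g Geometry (computed if missing).
#' @return Indices of the `n` cells whose centroids are closest to the
#'   area-weighted tissue center.
#' @export
central_cells <- function(t, n = 1L, g = compute_geometry(t)) {
  ctr <- colSums(g$centroid * g$area) / sum(g$area)
  d2 <- (g$centroid[, 1L] - ctr[1L])^2 + (g$centroid[, 2L] - ctr[2L])^2
  order(d2)[seq_len(n)]
}
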