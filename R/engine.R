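## Model specification and compilation -----------------------------------

#' Specify a multicellular model
#'
#' Bundles the arrows and parameters of a model.  Single-cell reactions
#' are replicated automatically into every cell at compile time;
#' intercellular arrows are expanded over the tissue topology; an optional
#' [grow_arrow()] switches the simulation to growing mode (vertex,
#' rest-length and dilution dynamics appended) and an optional
#' [division_spec()] enables threshold-triggered division.
#'
#' @param reactions List of `reaction` objects (mass-action or
#'   regulatory); [parse_arrow()] results may be spliced in directly.
#' @param intercellular List of intercellular arrows
#'   ([diffusion_arrow()], [transport_arrow()], [igrn_arrow()]).
#' @param species Named list describing each species:
#'   `list(init = , fixed = )` where `init` is a number or
#'   `function(tissue, geom)` returning per-cell values, and `fixed` is
#'   `FALSE`, `TRUE`, or `function(tissue, geom)` returning a logical
#'   per-cell mask (fixed entries are Dirichlet: held at their initial
#'   value).  Species appearing only in arrows default to
#'   `init = 0, fixed = FALSE`.
#' @param parameters Named list of numeric parameter values resolving the
#'   symbols used in rate laws.
#' @param grow `NULL` (static) or a [grow_arrow()].
#' @param divide `NULL` or a [division_spec()].
#' @param indicators `NULL` or `function(tissue, geom)` returning a named
#'   list of per-cell vectors (e.g. the L1/L2/TIP location indicators);
#'   re-evaluated after every division and available to rate callables as
#'   `ctx$ind`.
#' @return A `model_spec` object.
#' @export
model_spec <- function(reactions = list(), intercellular = list(),
                       species = list(), parameters = list(),
                       grow = NULL, divide = NULL, indicators = NULL) {
  ## flatten nested lists from parse_arrow()
  flat <- list()
  for (r in reactions) {
    if (inherits(r, "reaction")) flat <- c(flat, list(r))
    else flat <- c(flat, r)
  }
  stopifnot(all(vapply(flat, inherits, logical(1), "reaction")))
  stopifnot(all(vapply(intercellular, inherits, logical(1),
                       "intercellular_arrow")))
  if (!is.null(grow) && !inherits(grow, "grow_arrow"))
    stop_tessella("grow must be a grow_arrow()")
  if (!is.null(divide) && !inherits(divide, "division_spec"))
    stop_tessella("divide must be a division_spec()")
  arrow_sp <- unique(c(species_of(flat),
                       unlist(lapply(intercellular, function(a)
                         c(a$species, a$from, a$to)))))
  for (sp in arrow_sp)
    if (is.null(species[[sp]])) species[[sp]] <- list()
  species <- lapply(species, function(s)
    list(init = s$init %||% 0, fixed = s$fixed %||% FALSE))
  structure(list(reactions = flat, intercellular = intercellular,
                 species = species, parameters = parameters,
                 grow = grow, divide = divide, indicators = indicators),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec: ", length(x$reactions), " reactions, ",
      length(x$intercellular), " intercellular arrows, ",
      length(x$species), " species",
      if (!is.null(x$grow)) ", growing" else "",
      if (!is.null(x$divide)) ", dividing" else "", ">\n", sep = "")
  invisible(x)
}

init_conc <- function(model, t, g) {
  nsp <- length(model$species)
  C <- matrix(0, g$n_cells, nsp,
              dimnames = list(NULL, names(model$species)))
  for (sp in names(model$species)) {
    init <- model$species[[sp]]$init
    C[, sp] <- if (is.function(init)) init(t, g) else rep_len(init,
                                                             g$n_cells)
  }
  C
}

fixed_mask <- function(model, t, g) {
  nsp <- length(model$species)
  M <- matrix(FALSE, g$n_cells, nsp,
              dimnames = list(NULL, names(model$species)))
  for (sp in names(model$species)) {
    fx <- model$species[[sp]]$fixed
    M[, sp] <- if (is.function(fx)) fx(t, g) else rep_len(fx, g$n_cells)
  }
  M
}

#' Compile a model onto a tissue
#'
#' Expands every arrow over the tissue into one packed ODE system:
#' chemical state (all cells x species), and in growing mode the vertex
#' coordinates and per-edge rest lengths.  Fixed (Dirichlet) species
#' entries keep zero derivative.  The returned system carries the RHS
#' callable plus the packing/unpacking maps used by the simulation
#' drivers.
#'
#' @param model A [model_spec()].
#' @param t A `tissue`.
#' @param static Force static compilation; a grow/divide arrow present in
#'   static mode is a configuration error.
#' @param mech Optional `mech_state` carried over across a division
#'   (internal use).
#' @return An `ode_system` list.
#' @export
compile_model <- function(model, t, static = is.null(model$grow),
                          mech = NULL) {
  g <- compute_geometry(t)
  if (!static) g <- geom_with_accumulators(t, g)
  growing <- !static
  if (static && (!is.null(model$grow) || !is.null(model$divide)))
    stop_tessella("grow/divide arrows are not allowed in static mode")
  if (growing && is.null(model$grow))
    stop_tessella("growing mode needs a grow arrow")
  ind <- if (!is.null(model$indicators)) model$indicators(t, g)
  sp_names <- names(model$species)
  nsp <- length(sp_names)
  nc <- g$n_cells
  terms <- list()
  for (rx in model$reactions)
    terms <- c(terms, reaction_terms(rx, model$parameters)$terms)
  for (arrow in model$intercellular) {
    for (s in c(arrow$species, arrow$from, arrow$to))
      if (!s %in% sp_names)
        stop_tessella("intercellular arrow references undeclared species '%s'", s)
    terms <- c(terms,
               expand_intercellular(arrow, t, g, model$parameters)$terms)
  }
  termset <- new_ode_terms(terms)
  fixed <- fixed_mask(model, t, g)
  mech <- if (growing)
    mech %||% mech_state(t, g, k = model$grow$spring,
                         P = model$grow$pressure,
                         mu = model$grow$growth_rate)
  nv <- nrow(t$V); ne <- nrow(t$E)
  n_chem <- nc * nsp
  pack <- function(C, V = NULL, delta = NULL) {
    if (growing) c(as.vector(C), as.vector(V), delta) else as.vector(C)
  }
  unpack <- function(y) {
    C <- matrix(y[seq_len(n_chem)], nc, nsp,
                dimnames = list(NULL, sp_names))
    if (!growing) return(list(C = C))
    V <- matrix(y[n_chem + seq_len(2L * nv)], nv, 2L)
    delta <- y[n_chem + 2L * nv + seq_len(ne)]
    list(C = C, V = V, delta = delta)
  }
  base_ctx <- list(tissue = t, ind = ind, params = model$parameters)
  rhs <- function(tt, y) {
    s <- unpack(y)
    C <- s$C
    C[C < 0] <- 0
    if (growing) {
      G <- geom_metrics(g, t$E, s$V)
      G <- c(g[c("loop_cell", "loop_v", "loop_nx", "loop_edge",
                 "edge_cells", "boundary_edge", "adjacency",
                 "n_cells", "n_edges", "n_vertices",
                 "S_spring", "S_press", "S_cell")], G)
      m <- mech
      m$delta <- s$delta
      vel <- vertex_velocities(t, G, m, C,
                               ctx = c(base_ctx, list(geom = G, V = s$V)))
      ctx <- c(base_ctx, list(geom = G, V = s$V, velocities = vel))
      dC <- eval_terms(termset, C, tt, ctx)
      dA <- cell_area_rate(t, G, vel, V = s$V)
      dC <- dC - C * (dA / G$area)
      dC[fixed] <- 0
      ddelta <- rest_length_rates(m, G, C)
      c(as.vector(dC), as.vector(vel), ddelta)
    } else {
      ctx <- c(base_ctx, list(geom = g))
      dC <- eval_terms(termset, C, tt, ctx)
      dC[fixed] <- 0
      as.vector(dC)
    }
  }
  structure(list(rhs = rhs, pack = pack, unpack = unpack,
                 species = sp_names, n_cells = nc, geom = g,
                 tissue = t, fixed = fixed, growing = growing,
                 mech = mech, indicators = ind, model = model,
                 termset = termset),
            class = "ode_system")
}

#' @export
print.ode_system <- function(x, ...) {
  n <- x$n_cells * length(x$species) +
    if (x$growing) 2L * nrow(x$tissue$V) + nrow(x$tissue$E) else 0L
  cat("<ode_system: ", x$n_cells, " cells x ", length(x$species),
      " species", if (x$growing) " + mechanics", ", ", n,
      " state variables>\n", sep = "")
  invisible(x)
}
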