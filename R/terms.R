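## ODE term sets ---------------------------------------------------------
##
## An `ode_terms` object is the compiled form of a set of arrows: a flat
## list of additive flux terms, each attached to one species.  A term's
## `fn(C, t, ctx)` is vectorised over cells: `C` is an n_cells x n_species
## concentration matrix (named columns) and the term returns one value per
## cell.  Single-compartment models are simply the n_cells = 1 case.

new_ode_terms <- function(terms) structure(list(terms = terms),
                                           class = "ode_terms")

#' @export
print.ode_terms <- function(x, ...) {
  sp <- vapply(x$terms, `[[`, character(1), "species")
  cat("<ode_terms: ", length(x$terms), " terms over ",
      length(unique(sp)), " species>\n", sep = "")
  invisible(x)
}

#' @export
c.ode_terms <- function(...) {
  sets <- list(...)
  new_ode_terms(do.call(c, lapply(sets, `[[`, "terms")))
}

#' Evaluate an ODE term set
#'
#' Sums all flux terms of `terms` at concentration state `C`, returning the
#' chemical right-hand side \eqn{d[X]/dt} per cell and species.
#'
#' @param terms An `ode_terms` object (from [mass_action_terms()],
#'   [regulatory_terms()], [expand_diffusion()], ...).
#' @param C Concentration state: an n_cells x n_species matrix with column
#'   names, or a named vector (treated as a single compartment).
#' @param t Time (passed to time-dependent rate callables).
#' @param ctx Optional evaluation context (tissue, geometry, indicators)
#'   for context-dependent rates.
#' @return A matrix of the same shape as `C` (vector in, vector out).
#' @export
eval_terms <- function(terms, C, t = 0, ctx = NULL) {
  vec_in <- !is.matrix(C)
  if (vec_in) C <- matrix(C, nrow = 1L, dimnames = list(NULL, names(C)))
  dC <- matrix(0, nrow(C), ncol(C), dimnames = dimnames(C))
  for (tm in terms$terms) {
    v <- tm$fn(C, t, ctx)
    if (any(!is.finite(v)))
      stop_tessella("non-finite flux for species %s", tm$species)
    dC[, tm$species] <- dC[, tm$species] + v
  }
  if (vec_in) dC[1L, ] else dC
}

## Flux compilation ------------------------------------------------------

## Evaluate a resolved rate parameter at runtime: functions get the
## context, everything else is already numeric.
rate_val <- function(p, C, t, ctx) {
  if (is.function(p)) p(make_ctx(C, t, ctx)) else p
}

make_ctx <- function(C, t, ctx) {
  if (is.null(ctx)) list(C = C, t = t) else c(list(C = C, t = t), ctx)
}

check_T <- function(T, inputs) {
  if (is.numeric(T) && length(T) > 1L && length(T) != length(inputs))
    stop_tessella(
      "weight vector length %d does not match %d input species (%s)",
      length(T), length(inputs), paste(inputs, collapse = ", "))
  T
}

## Weighted inner product T . X^n over the input columns of C.
inner_tx <- function(C, inputs, T, n = 1) {
  T <- rep_len(T, length(inputs))
  n <- rep_len(n, length(inputs))
  z <- numeric(nrow(C))
  for (i in seq_along(inputs)) z <- z + T[i] * C[, inputs[i]]^n[i]
  z
}

## Compile one reaction's scalar flux g such that each species term is a
## signed multiple of g (signs depend on the law's coupling; see
## `reaction_terms`).  Returns function(C, t, ctx) -> per-cell vector.
compile_flux <- function(rx, parameters = list()) {
  law <- rx$rate
  kind <- class(law)[1L]
  P <- law
  for (nm in names(law)) {
    p <- law[[nm]]
    if (nm != "control" && !is.function(p) && !inherits(p, "rate_law"))
      P[[nm]] <- resolve_param(p, parameters)
  }
  enz <- rx$enzyme
  emul <- if (is.null(enz)) function(C) 1 else function(C) C[, enz]
  inputs <- names(rx$reactants)

  switch(kind,
    mass_action = {
      if (is.numeric(P$k) && any(P$k < 0))
        stop_tessella("negative mass-action rate constant")
      e <- as.numeric(rx$reactants)
      function(C, t, ctx) {
        k <- rate_val(P$k, C, t, ctx)
        k * col_power_prod(C, inputs, e) * emul(C)
      }
    },
    func = {
      function(C, t, ctx) P$g(C, t) * emul(C)
    },
    hill = {
      check_T(P$T, inputs)
      function(C, t, ctx) {
        z <- pmax(rate_val(P$a, C, t, ctx) + inner_tx(C, inputs, P$T), 0)
        v <- rate_val(P$v, C, t, ctx)
        zn <- z^P$n
        v * emul(C) * zn / (P$K^P$n + zn)
      }
    },
    grn = {
      check_T(P$T, inputs)
      f <- control_fn(law$control)
      function(C, t, ctx) {
        v <- rate_val(P$v, C, t, ctx)
        v * emul(C) * f(P$h + inner_tx(C, inputs, P$T, P$n))
      }
    },
    ssystem = {
      function(C, t, ctx) {
        np <- rep_len(P$np, length(inputs))
        nm <- rep_len(P$nm, length(inputs))
        (emul(C) / P$tau) *
          (P$Cp * col_power_prod(C, inputs, np) -
           P$Cm * col_power_prod(C, inputs, nm))
      }
    },
    nhca = {
      check_T(P$Tp, inputs); check_T(P$Tm, inputs)
      function(C, t, ctx) {
        Tp <- rep_len(P$Tp, length(inputs))
        Tm <- rep_len(P$Tm, length(inputs))
        n <- rep_len(P$n, length(inputs))
        up <- rep(1, nrow(C)); dn <- rep(1, nrow(C))
        for (i in seq_along(inputs)) {
          xn <- C[, inputs[i]]^n[i]
          up <- up * (1 + Tp[i] * xn)^P$m
          dn <- dn * (1 + Tm[i] * xn)^P$m
        }
        rate_val(P$v, C, t, ctx) * emul(C) * up / (P$k * dn + up)
      }
    },
    rational = {
      function(C, t, ctx) {
        a <- P$a; d <- P$d
        num <- rep(a[1L], nrow(C)); den <- rep(d[1L], nrow(C))
        if (length(a) > 1L)
          num <- num + inner_tx(C, inputs, a[-1L], P$n)
        if (length(d) > 1L)
          den <- den + inner_tx(C, inputs, d[-1L], P$m)
        num / den * emul(C)
      }
    },
    user = {
      check_T(P$T, inputs)
      function(C, t, ctx) {
        v <- rate_val(P$v, C, t, ctx)
        v * P$f(P$h - inner_tx(C, inputs, P$T, P$n)) * emul(C)
      }
    },
    mm = {
      if (length(inputs) != 1L)
        stop_tessella("MM law needs exactly one substrate")
      function(C, t, ctx) {
        X <- C[, inputs]
        rate_val(P$v, C, t, ctx) * emul(C) * X / (P$K + X)
      }
    },
    mwc = {
      if (length(inputs) != 1L)
        stop_tessella("MWC law needs exactly one substrate")
      function(C, t, ctx) {
        alpha <- C[, inputs] / P$K
        num <- alpha * (1 + alpha)^(P$n - 1) +
          P$L * P$c * alpha * (1 + P$c * alpha)^(P$n - 1)
        den <- (1 + alpha)^P$n + P$L * (1 + P$c * alpha)^P$n
        rate_val(P$k, C, t, ctx) * emul(C) * num / den
      }
    },
    stop_tessella("no flux rule for rate law '%s'", kind))
}

## Signed per-species multiples of the scalar flux for one reaction.
reaction_net <- function(rx) {
  kind <- class(rx$rate)[1L]
  if (kind %in% c("mass_action", "func")) {
    sp <- union(names(rx$reactants), names(rx$products))
    net <- numeric(length(sp)); names(net) <- sp
    if (length(rx$reactants))
      net[names(rx$reactants)] <- net[names(rx$reactants)] - rx$reactants
    if (length(rx$products))
      net[names(rx$products)] <- net[names(rx$products)] + rx$products
    net[net != 0]
  } else if (kind %in% c("mm", "mwc")) {
    net <- c(-1, 1)
    names(net) <- c(names(rx$reactants)[1L], names(rx$products)[1L])
    net
  } else {
    ## regulatory production: inputs are read, only products change
    net <- as.numeric(rx$products)
    names(net) <- names(rx$products)
    net
  }
}

## Terms for a single reaction under any rate law.
reaction_terms <- function(rx, parameters = list()) {
  flux <- compile_flux(rx, parameters)
  net <- reaction_net(rx)
  terms <- lapply(seq_along(net), function(i) {
    s <- net[[i]]
    list(species = names(net)[i],
         fn = function(C, t, ctx) s * flux(C, t, ctx))
  })
  new_ode_terms(terms)
}

#' Compile mass-action reactions into ODE terms
#'
#' Applies the mass-action rule: each reaction with reactant stoichiometries
#' \eqn{e_i} and products \eqn{f_j} contributes the term
#' \eqn{(f_j - e_j)\, k \prod_i X_i^{e_i}} to species \eqn{U_j}.
#'
#' @param reactions A list of `reaction` objects whose rate laws are all
#'   [mass_action()] (a single reaction is accepted).
#' @param parameters Named list resolving symbolic rate constants.
#' @return An `ode_terms` object; evaluate with [eval_terms()].
#' @examples
#' rts <- mass_action_terms(parse_arrow("A -> B", 2))
#' eval_terms(rts, c(A = 3, B = 0))   # d[A]/dt = -6, d[B]/dt = +6
#' @export
mass_action_terms <- function(reactions, parameters = list()) {
  if (inherits(reactions, "reaction")) reactions <- list(reactions)
  bad <- !vapply(reactions, function(r)
    inherits(r$rate, "mass_action"), logical(1))
  if (any(bad))
    stop_tessella("mass_action_terms: reaction(s) %s have non-mass-action laws",
                  paste(which(bad), collapse = ", "))
  do.call(c, lapply(reactions, reaction_terms, parameters = parameters))
}

#' Compile a regulatory reaction into ODE terms
#'
#' Emits the saturating rate-law term for a regulatory arrow: the pure
#' production laws (`hill`, `grn`, `ssystem`, `nhca`, `rational_law`,
#' `user_law`) add their flux to the product species only (inputs are read
#' but not consumed), while `mm`/`mwc` convert substrate to product
#' (\eqn{[Y]' = -[X]'}) and `func_rate` couples through the declared
#' stoichiometry.
#'
#' @param reaction A `reaction` whose rate law is a regulatory law.
#' @param parameters Named list resolving symbolic parameters.
#' @return An `ode_terms` object.
#' @examples
#' r <- reaction("X -> Y", hill(v = 1, n = 2, K = 0.5), enzyme = "E")
#' eval_terms(regulatory_terms(r), c(X = 0.5, Y = 0, E = 1))  # Y' = v/2
#' @export
regulatory_terms <- function(reaction, parameters = list()) {
  if (inherits(reaction$rate, "mass_action"))
    stop_tessella("use mass_action_terms() for mass-action reactions")
  reaction_terms(reaction, parameters)
}
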