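## Reaction arrows -------------------------------------------------------

new_reaction <- function(reactants, products, rate, enzyme = NULL) {
  stopifnot(inherits(rate, "rate_law"))
  if (length(reactants) == 0L && length(products) == 0L)
    stop_tessella("a reaction needs at least one reactant or product")
  if (length(reactants) && (any(reactants <= 0) ||
                            any(reactants != round(reactants))))
    stop_tessella("reactant stoichiometries must be positive integers")
  if (length(products) && (any(products <= 0) ||
                           any(products != round(products))))
    stop_tessella("product stoichiometries must be positive integers")
  structure(list(reactants = reactants, products = products,
                 rate = rate, enzyme = enzyme),
            class = "reaction")
}

#' @export
print.reaction <- function(x, ...) {
  side <- function(s) {
    if (!length(s)) return("0")
    paste(ifelse(s > 1L, paste0(s, " "), ""), names(s),
          sep = "", collapse = " + ")
  }
  cat(side(x$reactants), "->", side(x$products))
  if (!is.null(x$enzyme)) cat(" [enzyme:", x$enzyme, "]")
  cat("  ", format(class(x$rate)[1L]), "\n")
  invisible(x)
}

parse_side <- function(txt, arrow_txt) {
  txt <- trimws(txt)
  if (txt == "0" || txt == "") return(integer(0))
  terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1L]])
  out <- integer(0)
  for (tm in terms) {
    m <- regmatches(tm, regexec("^([0-9]*)\\s*([A-Za-z_][A-Za-z0-9_.]*)$", tm))[[1L]]
    if (length(m) != 3L)
      stop_tessella("cannot parse term '%s' in arrow '%s'", tm, arrow_txt)
    st <- if (m[2L] == "") 1L else as.integer(m[2L])
    sp <- m[3L]
    if (st < 1L)
      stop_tessella("zero stoichiometry for '%s' in arrow '%s'", sp, arrow_txt)
    out[sp] <- (if (sp %in% names(out)) out[[sp]] else 0L) + st
  }
  out
}

#' Parse a reaction arrow expression
#'
#' Arrows are written in plain text: `"A -> B"`, `"2A + B -> 3A"`,
#' `"0 -> A"` (zeroth-order source), `"A -> 0"` (degradation), and the
#' reversible form `"A <-> B"`, which expands to a pair of opposed
#' irreversible reactions and therefore needs two rate laws (forward,
#' backward).  An unadorned number supplied as `rate` is shorthand for
#' [mass_action()].
#'
#' @param spec Character arrow expression.
#' @param rate A [rate_laws] object (or bare rate constant) for an
#'   irreversible arrow; a list of two for a reversible arrow.
#' @param enzyme Optional enzyme species name: the flux is multiplied by
#'   its concentration (regulatory laws of Table-style `X ↦ᴇ Y` forms).
#' @return A list of `reaction` objects (length 1, or 2 when reversible).
#' @examples
#' parse_arrow("A -> B", 2)
#' parse_arrow("A <-> B", list(1, 0.5))
#' parse_arrow("2A + B -> 3A", mass_action("c"))
#' @export
parse_arrow <- function(spec, rate, enzyme = NULL) {
  stopifnot(is.character(spec), length(spec) == 1L)
  as_law <- function(r) {
    if (inherits(r, "rate_law")) r
    else if (is.numeric(r) || is.character(r) || is.function(r)) mass_action(r)
    else stop_tessella("invalid rate for arrow '%s'", spec)
  }
  if (grepl("<->", spec, fixed = TRUE)) {
    sides <- strsplit(spec, "<->", fixed = TRUE)[[1L]]
    if (length(sides) != 2L)
      stop_tessella("malformed reversible arrow '%s'", spec)
    if (!is.list(rate) || inherits(rate, "rate_law") || length(rate) != 2L)
      stop_tessella(
        "reversible arrow '%s' needs a list of 2 rate laws (got %d)",
        spec, if (is.list(rate) && !inherits(rate, "rate_law"))
          length(rate) else 1L)
    lhs <- parse_side(sides[1L], spec)
    rhs <- parse_side(sides[2L], spec)
    list(new_reaction(lhs, rhs, as_law(rate[[1L]]), enzyme),
         new_reaction(rhs, lhs, as_law(rate[[2L]]), enzyme))
  } else if (grepl("->", spec, fixed = TRUE)) {
    sides <- strsplit(spec, "->", fixed = TRUE)[[1L]]
    if (length(sides) != 2L)
      stop_tessella("malformed arrow '%s'", spec)
    if (is.list(rate) && !inherits(rate, "rate_law"))
      stop_tessella("irreversible arrow '%s' takes a single rate law", spec)
    list(new_reaction(parse_side(sides[1L], spec),
                      parse_side(sides[2L], spec), as_law(rate), enzyme))
  } else {
    stop_tessella("unknown arrow head in '%s' (expected -> or <->)", spec)
  }
}

#' Declare a reaction
#'
#' Convenience wrapper around [parse_arrow()] for the common irreversible
#' case; returns a single `reaction` rather than a list.
#'
#' @inheritParams parse_arrow
#' @return A `reaction` object.
#' @export
reaction <- function(spec, rate, enzyme = NULL) {
  r <- parse_arrow(spec, rate, enzyme)
  if (length(r) != 1L)
    stop_tessella("use parse_arrow() for reversible arrows")
  r[[1L]]
}

## Catalytic arrow forms -------------------------------------------------

#' Catalytic and cascade arrow forms
#'
#' Compact enzymatic arrows that expand into elementary mass-action steps
#' with explicitly generated bound-complex species:
#'
#' * `catalytic_arrow(X, Y, E, rates)` — the four-step scheme
#'   `X + E <-> X_E`, `X_E <-> Y + E` (rates
#'   \eqn{k_1,\dots,k_4}).
#' * `catalytic_arrow(..., intermediate = TRUE)` — the six-step scheme
#'   with both complexes: `X + E <-> X_E`, `X_E <-> Y_E`,
#'   `Y_E <-> Y + E`.
#' * `double_catalytic_arrow(X, Y, E, F, rates)` — forward catalysis by
#'   `E` and reverse catalysis by `F` (8 rates).
#' * `cascade_arrow(chain, E, rates)` — `X <-> Y <-> Z <-> ...` all
#'   catalysed by `E`, expanded pairwise.
#'
#' Complex names join substrate and enzyme with an underscore (`X_E`); on
#' collision with an existing species a numeric suffix is appended
#' (`X_E2`).  Use [expand_catalytic()] to perform the expansion.
#'
#' @param substrate,product,chain Species names.
#' @param enzyme,enzyme_fwd,enzyme_rev Enzyme species names.
#' @param rates Vector/list of rate constants for the generated elementary
#'   steps, in the order the steps are listed above.
#' @param intermediate Use the six-step (double complex) scheme.
#' @return An object of class `catalytic_arrow`.
#' @export
catalytic_arrow <- function(substrate, product, enzyme, rates,
                            intermediate = FALSE) {
  need <- if (intermediate) 6L else 4L
  if (length(rates) != need)
    stop_tessella("catalytic arrow %s -> %s needs %d rate constants, got %d",
                  substrate, product, need, length(rates))
  structure(list(form = if (intermediate) "catint" else "cat",
                 substrate = substrate, product = product,
                 enzyme = enzyme, rates = as.list(rates)),
            class = "catalytic_arrow")
}

#' @rdname catalytic_arrow
#' @export
double_catalytic_arrow <- function(substrate, product, enzyme_fwd,
                                   enzyme_rev, rates) {
  if (length(rates) != 8L)
    stop_tessella("double catalytic arrow needs 8 rate constants, got %d",
                  length(rates))
  structure(list(form = "cat2", substrate = substrate, product = product,
                 enzyme = enzyme_fwd, enzyme_rev = enzyme_rev,
                 rates = as.list(rates)),
            class = "catalytic_arrow")
}

#' @rdname catalytic_arrow
#' @export
cascade_arrow <- function(chain, enzyme, rates, enzyme_rev = NULL) {
  if (length(chain) < 2L)
    stop_tessella("a cascade needs at least two species")
  per <- if (is.null(enzyme_rev)) 4L else 8L
  need <- per * (length(chain) - 1L)
  if (length(rates) != need)
    stop_tessella("cascade over %d species needs %d rate constants, got %d",
                  length(chain), need, length(rates))
  structure(list(form = "cascade", chain = chain, enzyme = enzyme,
                 enzyme_rev = enzyme_rev, rates = as.list(rates)),
            class = "catalytic_arrow")
}

complex_name <- function(substrate, enzyme, existing) {
  base <- paste(substrate, enzyme, sep = "_")
  nm <- base
  i <- 1L
  while (nm %in% existing) {
    i <- i + 1L
    nm <- paste0(base, i)
  }
  nm
}

#' Expand a catalytic arrow into elementary reactions
#'
#' @param arrow A [catalytic_arrow()] / [double_catalytic_arrow()] /
#'   [cascade_arrow()] object.
#' @param existing Character vector of species names already in use
#'   (generated complex names avoid them deterministically).
#' @return A list of irreversible mass-action `reaction` objects.
#' @examples
#' # X ⇄[E] Y: four elementary steps over {X, E, X_E, Y}
#' expand_catalytic(catalytic_arrow("X", "Y", "E", c(1, 1, 1, 1)))
#' @export
expand_catalytic <- function(arrow, existing = character()) {
  stopifnot(inherits(arrow, "catalytic_arrow"))
  rev_pair <- function(lhs, rhs, k1, k2) {
    c(parse_arrow(paste(lhs, "->", rhs), k1),
      parse_arrow(paste(rhs, "->", lhs), k2))
  }
  switch(arrow$form,
    cat = {
      XE <- complex_name(arrow$substrate, arrow$enzyme, existing)
      r <- arrow$rates
      c(rev_pair(paste(arrow$substrate, "+", arrow$enzyme), XE,
                 r[[1L]], r[[2L]]),
        rev_pair(XE, paste(arrow$product, "+", arrow$enzyme),
                 r[[3L]], r[[4L]]))
    },
    catint = {
      XE <- complex_name(arrow$substrate, arrow$enzyme, existing)
      YE <- complex_name(arrow$product, arrow$enzyme, c(existing, XE))
      r <- arrow$rates
      c(rev_pair(paste(arrow$substrate, "+", arrow$enzyme), XE,
                 r[[1L]], r[[2L]]),
        rev_pair(XE, YE, r[[3L]], r[[4L]]),
        rev_pair(YE, paste(arrow$product, "+", arrow$enzyme),
                 r[[5L]], r[[6L]]))
    },
    cat2 = {
      r <- arrow$rates
      fwd <- catalytic_arrow(arrow$substrate, arrow$product, arrow$enzyme,
                             r[1:4])
      bwd <- catalytic_arrow(arrow$product, arrow$substrate,
                             arrow$enzyme_rev, r[5:8])
      fwd_rx <- expand_catalytic(fwd, existing)
      c(fwd_rx, expand_catalytic(bwd, c(existing, species_of(fwd_rx))))
    },
    cascade = {
      out <- list()
      used <- existing
      per <- if (is.null(arrow$enzyme_rev)) 4L else 8L
      for (i in seq_len(length(arrow$chain) - 1L)) {
        r <- arrow$rates[((i - 1L) * per + 1L):(i * per)]
        step <- if (is.null(arrow$enzyme_rev))
          catalytic_arrow(arrow$chain[i], arrow$chain[i + 1L],
                          arrow$enzyme, r)
        else
          double_catalytic_arrow(arrow$chain[i], arrow$chain[i + 1L],
                                 arrow$enzyme, arrow$enzyme_rev, r)
        rx <- expand_catalytic(step, used)
        used <- c(used, species_of(rx))
        out <- c(out, rx)
      }
      out
    },
    stop_tessella("unknown catalytic arrow form '%s'", arrow$form))
}

#' Species mentioned by a list of reactions
#'
#' @param reactions A list of `reaction` objects (a single reaction is
#'   accepted).
#' @return Character vector of species names, in first-appearance order
#'   (enzymes included).
#' @export
species_of <- function(reactions) {
  if (inherits(reactions, "reaction")) reactions <- list(reactions)
  out <- character(0)
  for (r in reactions)
    out <- c(out, names(r$reactants), names(r$products), r$enzyme)
  unique(out)
}
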