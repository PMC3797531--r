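## Model configuration files ----------------------------------------------
##
## Models can be described in a TOML config (subset: [table] /
## [[array-of-table]] headers, `key = value` pairs with strings, numbers,
## booleans and flat arrays, `#` comments).  No TOML package exists in
## the supported environment, so the subset is parsed here.

toml_value <- function(txt) {
  txt <- trimws(txt)
  if (txt == "true") return(TRUE)
  if (txt == "false") return(FALSE)
  if (grepl('^".*"$', txt)) return(substr(txt, 2L, nchar(txt) - 1L))
  if (grepl("^\\[.*\\]$", txt)) {
    inner <- trimws(substr(txt, 2L, nchar(txt) - 1L))
    if (inner == "") return(list())
    parts <- strsplit(inner, ",")[[1L]]
    vals <- lapply(parts, toml_value)
    if (all(vapply(vals, is.numeric, logical(1))))
      return(unlist(vals))
    return(vals)
  }
  num <- suppressWarnings(as.numeric(txt))
  if (!is.na(num)) return(num)
  stop_tessella("cannot parse TOML value: %s", txt)
}

#' Read a TOML-subset configuration file
#'
#' Supports `[table]` and `[[array-of-table]]` headers (dotted names
#' nest), `key = value` pairs with strings, numbers, booleans and flat
#' arrays, and `#` comments — the subset used by the model configuration
#' schema (see [model_from_config()]).
#'
#' @param path File path.
#' @return A nested named list.
#' @export
read_toml <- function(path) {
  lines <- readLines(path)
  out <- list()
  cur_path <- character(0)
  cur_is_array <- FALSE
  set_in <- function(x, keys, value) {
    if (!length(keys)) return(value)
    k <- keys[1L]
    x[[k]] <- set_in(x[[k]] %||% list(), keys[-1L], value)
    x
  }
  get_in <- function(x, keys) {
    for (k in keys) x <- x[[k]] %||% list()
    x
  }
  assign_kv <- function(key, value) {
    keys <- cur_path
    if (cur_is_array) {
      arr <- get_in(out, keys)
      arr[[length(arr)]][[key]] <- value
      out <<- set_in(out, keys, arr)
    } else {
      out <<- set_in(out, c(keys, key), value)
    }
  }
  for (raw in lines) {
    line <- sub("#.*$", "", raw)
    line <- trimws(line)
    if (line == "") next
    if (grepl("^\\[\\[.*\\]\\]$", line)) {
      name <- trimws(gsub("^\\[\\[|\\]\\]$", "", line))
      cur_path <- strsplit(name, ".", fixed = TRUE)[[1L]]
      cur_is_array <- TRUE
      arr <- get_in(out, cur_path)
      arr[[length(arr) + 1L]] <- list()
      out <- set_in(out, cur_path, arr)
    } else if (grepl("^\\[.*\\]$", line)) {
      name <- trimws(gsub("^\\[|\\]$", "", line))
      cur_path <- strsplit(name, ".", fixed = TRUE)[[1L]]
      cur_is_array <- FALSE
    } else if (grepl("=", line, fixed = TRUE)) {
      eq <- regexpr("=", line, fixed = TRUE)
      key <- trimws(substr(line, 1L, eq - 1L))
      assign_kv(key, toml_value(substr(line, eq + 1L, nchar(line))))
    } else {
      stop_tessella("cannot parse TOML line: %s", raw)
    }
  }
  out
}

config_rate_law <- function(spec, parameters) {
  law <- spec$law %||% "mass_action"
  args <- spec[setdiff(names(spec), c("arrow", "rate", "law", "enzyme"))]
  switch(law,
    mass_action = mass_action(spec$rate),
    hill = do.call(hill, args),
    grn = do.call(grn, args),
    ssystem = do.call(ssystem, args),
    nhca = do.call(nhca, args),
    rational = do.call(rational_law, args),
    mm = do.call(mm, args),
    mwc = do.call(mwc, args),
    stop_tessella("unknown rate law '%s' in config", law))
}

affine_or_const <- function(v, builder) {
  ## numeric scalar, or [base, slope, "SPECIES"] affine feedback
  if (is.numeric(v) && length(v) == 1L) return(v)
  if (is.list(v) && length(v) == 3L && is.character(v[[3L]]))
    return(builder(v[[3L]], v[[1L]], v[[2L]]))
  stop_tessella("expected a number or [base, slope, \"species\"]")
}

#' Build a model from a configuration file
#'
#' The `[model]` table selects `type`: one of the packaged demonstration
#' models (`"brusselator"`, `"wus"`, `"organizer"`, with `[parameters]`
#' passed as constructor arguments) or `"custom"`.  A custom model lists
#' `[[reaction]]` tables (`arrow`, `rate` — a number, parameter symbol,
#' or two-element array for reversible arrows — and optionally `law` with
#' its named arguments and `enzyme`), `[[diffusion]]` / `[[transport]]` /
#' `[[igrn]]` tables mirroring the arrow constructors,
#' `[species.<name>]` tables (`init`, `fixed`), a `[parameters]` table,
#' and optional `[grow]` (`pressure`, `growth_rate`, `spring`: numbers or
#' `[base, slope, "W"]` affine feedback triples) and `[divide]` tables.
#'
#' @param config Path to a TOML config, or an already-parsed list.
#' @return A [model_spec()].
#' @export
model_from_config <- function(config) {
  cfg <- if (is.character(config)) read_toml(config) else config
  type <- cfg$model$type %||% "custom"
  pars <- cfg$parameters %||% list()
  if (type != "custom") {
    ctor <- switch(type, brusselator = brusselator_model,
                   wus = wus_model, organizer = organizer_growth_model,
                   stop_tessella("unknown model type '%s'", type))
    return(do.call(ctor, pars))
  }
  reactions <- list()
  for (rx in cfg$reaction %||% list()) {
    law <- cfg_law <- rx$law %||% "mass_action"
    if (identical(cfg_law, "mass_action")) {
      rate <- rx$rate
      if (is.list(rate) || length(rate) == 2L)
        reactions <- c(reactions,
                       parse_arrow(rx$arrow, as.list(rate)))
      else reactions <- c(reactions, parse_arrow(rx$arrow, rate))
    } else {
      reactions <- c(reactions,
                     list(reaction(rx$arrow, config_rate_law(rx, pars),
                                   enzyme = rx$enzyme)))
    }
  }
  ic <- c(lapply(cfg$diffusion %||% list(), function(d)
            diffusion_arrow(d$species, PI = d$PI, PO = d$PO)),
          lapply(cfg$transport %||% list(), function(d)
            transport_arrow(d$species, f_out = d$f_out, f_in = d$f_in)),
          lapply(cfg$igrn %||% list(), function(d)
            igrn_arrow(d$from, d$to, v = d$v, T = d$T,
                       n = d$n %||% 1, h = d$h %||% 0)))
  species <- lapply(cfg$species %||% list(), function(s)
    list(init = s$init %||% 0, fixed = s$fixed %||% FALSE))
  grow <- if (!is.null(cfg$grow))
    grow_arrow(
      pressure = affine_or_const(cfg$grow$pressure %||% 0,
                                 pressure_feedback),
      growth_rate = affine_or_const(cfg$grow$growth_rate %||% 0,
                                    growth_feedback),
      spring = cfg$grow$spring %||% 1)
  divide <- if (!is.null(cfg$divide))
    division_spec(model = cfg$divide$model %||% "errera",
                  variable = cfg$divide$variable %||% "area",
                  mean = cfg$divide$mean,
                  sd = cfg$divide$sd %||% 0,
                  weights = cfg$divide$weights %||% c(1, 1, 0, 0),
                  eps_L = cfg$divide$eps_L %||% 0.1,
                  eps_perp = cfg$divide$eps_perp %||% 0.1)
  model_spec(reactions = reactions, intercellular = ic,
             species = species, parameters = pars, grow = grow,
             divide = divide,
             indicators = function(t, g) classify_layers(t, g))
}
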