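`%||%` <- function(a, b) if (is.null(a)) b else a

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' @keywords internal
stop_tessella <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## Sum `vals` (vector or 2-col matrix of per-item contributions) into an
## accumulator of `n` slots at positions `idx` (duplicates allowed).
add_at <- function(n, idx, vals) {
  if (is.matrix(vals)) {
    out <- matrix(0, n, ncol(vals))
    if (length(idx)) {
      s <- rowsum(vals, group = idx, reorder = FALSE)
      out[as.integer(rownames(s)), ] <- s
    }
    out
  } else {
    out <- numeric(n)
    if (length(idx)) {
      s <- rowsum(vals, group = idx, reorder = FALSE)
      out[as.integer(rownames(s))] <- s[, 1L]
    }
    out
  }
}

## Resolve a rate parameter: numeric stays, character looked up in the
## model parameter table, functions pass through untouched.
resolve_param <- function(p, parameters, what = "parameter") {
  if (is.function(p)) return(p)
  if (is.character(p)) {
    miss <- setdiff(p, names(parameters))
    if (length(miss))
      stop_tessella("unresolved %s symbol(s): %s", what,
                    paste(miss, collapse = ", "))
    return(unlist(parameters[p], use.names = FALSE))
  }
  if (is.numeric(p)) return(p)
  stop_tessella("invalid %s value of class %s", what, class(p)[1L])
}

## Row-wise product of selected columns raised to powers (mass action).
col_power_prod <- function(C, cols, pow) {
  out <- rep(1, nrow(C))
  for (i in seq_along(cols)) out <- out * C[, cols[i]]^pow[i]
  out
}
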