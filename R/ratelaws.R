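## Rate laws -------------------------------------------------------------
##
## Every rate law is a small S3 object holding named parameters.  Parameters
## may be numbers, character symbols resolved against the model-wide
## parameter table at compile time, or functions of the evaluation context
## (see `compile_flux`) for per-cell / indicator-dependent rates.

new_rate_law <- function(.kind, ...) {
  ## formal deliberately dotted: plain `kind` would partial-match the
  ## `k = ` parameter of mass_action/nhca/mwc
  structure(list(...), class = c(.kind, "rate_law"))
}

#' Rate-law constructors
#'
#' Constructors for the rate laws understood by the arrow compiler.
#' `mass_action(k)` is the elementary law: the reaction flux is
#' \eqn{k \prod_i X_i^{e_i}} over the reactants with their stoichiometries,
#' and each species \eqn{U_j} receives the term \eqn{(f_j - e_j)} times the
#' flux.  The regulatory laws (`hill`, `grn`, `ssystem`, `nhca`,
#' `rational_law`, `user_law`) produce their product species at the stated
#' saturating rate without consuming their inputs; `mm` (Michaelis-Menten)
#' and `mwc` (Monod-Wyman-Changeux) convert a substrate into a product,
#' so \eqn{[Y]' = -[X]'}.  `func_rate(g)` couples an arbitrary flux
#' \eqn{g(X)} to the reaction stoichiometry.
#'
#' Parameters may be numbers, character names resolved from the model's
#' parameter table, or functions of the compile context (for per-cell
#' rates such as indicator-gated production).  Weight vectors `T` for the
#' multi-input laws are matched positionally against the reaction's input
#' species.
#'
#' @param k,v,n,K,a,T,h,tau,Cp,Cm,np,nm,Tp,Tm,m,c,L,d,f,g Law parameters;
#'   see Details.
#' @param control Control function for `grn`: `"logistic"`
#'   (\eqn{1/(1+e^{-x})}) or `"sigma"`
#'   (\eqn{(1 + x/\sqrt{1+x^2})/2}), both monotone increasing,
#'   saturating, and equal to 1/2 at 0.
#' @return A `rate_law` object.
#' @details
#' * `hill(v, n, K, a, T)`: \eqn{v[\mathcal{E}](a + T\cdot X)^n /
#'   (K^n + (a + T\cdot X)^n)}.
#' * `grn(v, T, n, h, control)`: \eqn{v[\mathcal{E}] f(h + \sum_i T_i X_i^n)}
#'   with `f` the control function.
#' * `ssystem(tau, Cp, Cm, np, nm)`: \eqn{([\mathcal{E}]/\tau)(C^+ \prod_i
#'   X_i^{n^+_i} - C^- \prod_i X_i^{n^-_i})}.
#' * `nhca(v, Tp, Tm, n, m, k)`: \eqn{v[\mathcal{E}] \prod_i (1 + T^+_i
#'   X_i^{n_i})^m / (k \prod_i (1 + T^-_i X_i^{n_i})^m + \prod_i (1 + T^+_i
#'   X_i^{n_i})^m)}.
#' * `rational_law(a, d, n, m)`: \eqn{(a_0 + \sum_i a_i X_i^{n_i}) /
#'   (d_0 + \sum_i d_i X_i^{m_i})}.
#' * `user_law(v, T, n, h, f)`: \eqn{v f(h - T\cdot X^n)}.
#' * `mm(K, v)`: \eqn{v[\mathcal{E}] X/(K + X)}.
#' * `mwc(k, n, c, L, K)`: concerted allosteric rate with
#'   \eqn{\alpha = X/K}.
#' @examples
#' mass_action(2)
#' hill(v = 1, n = 2, K = 0.5)
#' grn(v = 0.1, T = c(-25, 0.5), n = 1, h = 0, control = "sigma")
#' @name rate_laws
NULL

#' @rdname rate_laws
#' @export
mass_action <- function(k) new_rate_law("mass_action", k = k)

#' @rdname rate_laws
#' @export
hill <- function(v, n, K, a = 0, T = 1)
  new_rate_law("hill", v = v, n = n, K = K, a = a, T = T)

#' @rdname rate_laws
#' @export
grn <- function(v, T, n = 1, h = 0, control = c("logistic", "sigma")) {
  control <- match.arg(control)
  new_rate_law("grn", v = v, T = T, n = n, h = h, control = control)
}

#' @rdname rate_laws
#' @export
ssystem <- function(tau, Cp, Cm, np, nm)
  new_rate_law("ssystem", tau = tau, Cp = Cp, Cm = Cm, np = np, nm = nm)

#' @rdname rate_laws
#' @export
nhca <- function(v, Tp, Tm, n, m = 1, k = 1)
  new_rate_law("nhca", v = v, Tp = Tp, Tm = Tm, n = n, m = m, k = k)

#' @rdname rate_laws
#' @export
rational_law <- function(a, d, n = 1, m = n)
  new_rate_law("rational", a = a, d = d, n = n, m = m)

#' @rdname rate_laws
#' @export
user_law <- function(v, T, n, h, f) {
  stopifnot(is.function(f))
  new_rate_law("user", v = v, T = T, n = n, h = h, f = f)
}

#' @rdname rate_laws
#' @export
mm <- function(K, v) new_rate_law("mm", K = K, v = v)

#' @rdname rate_laws
#' @export
mwc <- function(k, n, c, L, K)
  new_rate_law("mwc", k = k, n = n, c = c, L = L, K = K)

#' @rdname rate_laws
#' @export
func_rate <- function(g) {
  stopifnot(is.function(g))
  new_rate_law("func", g = g)
}

#' @export
print.rate_law <- function(x, ...) {
  ps <- vapply(x, function(p) {
    if (is.function(p)) "<fn>" else paste(format(p), collapse = ",")
  }, character(1))
  cat("<rate law ", class(x)[1L], "(",
      paste(names(ps), ps, sep = "=", collapse = ", "), ")>\n", sep = "")
  invisible(x)
}

#' Control functions for GRN-family laws
#'
#' `ctrl_logistic(x)` is the logistic function \eqn{1/(1+e^{-x})};
#' `ctrl_sigma(x) = (1 + x/\sqrt{1+x^2})/2` is an algebraic alternative.
#' Both are monotone increasing, map onto (0, 1), and equal 1/2 at 0.
#'
#' @param x Numeric vector.
#' @return Numeric vector in (0, 1).
#' @export
ctrl_logistic <- function(x) 1 / (1 + exp(-x))

#' @rdname ctrl_logistic
#' @export
ctrl_sigma <- function(x) (1 + x / sqrt(1 + x^2)) / 2

control_fn <- function(name) {
  switch(name, logistic = ctrl_logistic, sigma = ctrl_sigma,
         stop_tessella("unknown control function '%s'", name))
}
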