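## Adaptive explicit ODE integration -------------------------------------
##
## Dormand-Prince 5(4) pair with step-size control, cubic Hermite dense
## output for sampling, and terminal event location (sign upcrossings of
## a vector event function, refined by bisection on the interpolant).
## Written here because no ODE solver package is available in the target
## environment; tolerances follow the engine defaults (rtol 1e-6,
## atol 1e-9).

dp_A <- list(
  c(1/5),
  c(3/40, 9/40),
  c(44/45, -56/15, 32/9),
  c(19372/6561, -25360/2187, 64448/6561, -212/729),
  c(9017/3168, -355/33, 46732/5247, 49/176, -5103/18656),
  c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84))
dp_c <- c(1/5, 3/10, 4/5, 8/9, 1, 1)
dp_b5 <- c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84, 0)
dp_b4 <- c(5179/57600, 0, 7571/16695, 393/640, -92097/339200, 187/2100, 1/40)

hermite_interp <- function(t0, y0, f0, t1, y1, f1, ts) {
  h <- t1 - t0
  th <- (ts - t0) / h
  h00 <- (1 + 2 * th) * (1 - th)^2
  h10 <- th * (1 - th)^2
  h01 <- th^2 * (3 - 2 * th)
  h11 <- th^2 * (th - 1)
  h00 * y0 + h10 * h * f0 + h01 * y1 + h11 * h * f1
}

#' Integrate an ODE system (Dormand-Prince RK45)
#'
#' @param rhs Function `f(t, y)` returning `dy/dt`.
#' @param y0 Initial state vector.
#' @param t0,t1 Time span.
#' @param rtol,atol Relative/absolute error tolerances.
#' @param save_at Times at which to sample the solution (dense output);
#'   defaults to `c(t0, t1)`.
#' @param events Optional event function `g(t, y)` returning a numeric
#'   vector; integration stops at the first zero upcrossing (a component
#'   passing from negative to non-negative), located by bisection.
#' @param h0 Initial step (heuristic default).
#' @param hmax Maximum step size.
#' @param max_steps Step budget; exceeding it is an error reporting the
#'   reached time and state norm.
#' @return List with `t` (sampled times), `y` (matrix, one row per
#'   sample), and `event` (`NULL`, or a list with `time`, `state`,
#'   `index` of the crossing component).
#' @export
ode_rk45 <- function(rhs, y0, t0, t1, rtol = 1e-6, atol = 1e-9,
                     save_at = NULL, events = NULL, h0 = NULL,
                     hmax = Inf, max_steps = 1e6L) {
  y <- as.numeric(y0)
  n <- length(y)
  t <- t0
  f <- rhs(t, y)
  if (length(f) != n) stop_tessella("rhs dimension mismatch")
  save_at <- sort(unique(save_at %||% c(t0, t1)))
  save_at <- save_at[save_at >= t0 - 1e-12 & save_at <= t1 + 1e-12]
  out_t <- numeric(0); out_y <- list()
  nxt <- 1L
  emit_upto <- function(ta, ya, fa, tb, yb, fb) {
    while (nxt <= length(save_at) && save_at[nxt] <= tb + 1e-12) {
      ts <- save_at[nxt]
      ys <- if (ts <= ta) ya else if (ts >= tb) yb
            else hermite_interp(ta, ya, fa, tb, yb, fb, ts)
      out_t[length(out_t) + 1L] <<- ts
      out_y[[length(out_y) + 1L]] <<- ys
      nxt <<- nxt + 1L
    }
  }
  if (length(save_at) && save_at[1L] <= t0 + 1e-12) {
    out_t <- t0; out_y <- list(y); nxt <- 2L
  }
  g_old <- if (!is.null(events)) events(t, y)
  h <- h0 %||% min(max((t1 - t0) * 1e-4, 1e-8), hmax, t1 - t0)
  steps <- 0L
  while (t < t1 - 1e-12 * max(1, abs(t1))) {
    steps <- steps + 1L
    if (steps > max_steps)
      stop_tessella(
        "integration failed: step budget exhausted at t=%.6g (|y|=%.3g)",
        t, sqrt(sum(y^2)))
    h <- min(h, t1 - t, hmax)
    ks <- matrix(0, 7L, n)
    ks[1L, ] <- f
    for (s in 1:6) {
      yi <- y + h * (if (s == 1L) dp_A[[1L]] * ks[1L, ]
                     else colSums(dp_A[[s]] * ks[1:s, , drop = FALSE]))
      ks[s + 1L, ] <- rhs(t + dp_c[s] * h, yi)
    }
    y5 <- y + h * colSums(dp_b5 * ks)
    y4 <- y + h * colSums(dp_b4 * ks)
    sc <- atol + rtol * pmax(abs(y), abs(y5))
    err <- sqrt(mean(((y5 - y4) / sc)^2))
    if (!is.finite(err)) { h <- h / 2; f <- rhs(t, y); next }
    if (err <= 1) {
      t_new <- t + h
      f_new <- ks[7L, ]   # FSAL: k7 = f(t+h, y5)
      if (!is.null(events)) {
        g_new <- events(t_new, y5)
        cross <- which(g_old < 0 & g_new >= 0)
        if (length(cross)) {
          ## bisection on the Hermite interpolant, first-crossing component
          ga <- g_old; ta <- t; tb <- t_new
          for (it in 1:60) {
            tm <- (ta + tb) / 2
            ym <- hermite_interp(t, y, f, t_new, y5, f_new, tm)
            gm <- events(tm, ym)
            if (any(gm[cross] >= 0)) tb <- tm else { ta <- tm }
            if (tb - ta < 1e-12 * max(1, abs(tb))) break
          }
          te <- tb
          ye <- hermite_interp(t, y, f, t_new, y5, f_new, te)
          ge <- events(te, ye)
          pos <- cross[ge[cross] >= 0]
          idx <- if (length(pos)) min(pos) else cross[which.max(ge[cross])]
          emit_upto(t, y, f, te, ye, rhs(te, ye))
          return(list(t = out_t,
                      y = do.call(rbind, out_y),
                      t_final = te, y_final = ye,
                      event = list(time = te, state = ye, index = idx)))
        }
        g_old <- g_new
      }
      emit_upto(t, y, f, t_new, y5, f_new)
      t <- t_new; y <- y5; f <- f_new
      h <- h * min(5, max(0.2, 0.9 * err^(-0.2)))
    } else {
      h <- h * max(0.2, 0.9 * err^(-0.2))
    }
  }
  if (nxt <= length(save_at)) emit_upto(t, y, f, t, y, f)
  list(t = out_t, y = do.call(rbind, out_y), t_final = t, y_final = y,
       event = NULL)
}
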