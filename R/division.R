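## Cell division ---------------------------------------------------------
##
## Division triggers when a cell's area (or a chosen constituent) crosses
## a normally distributed threshold assigned at birth.  The new wall is a
## straight chord placed either by the modern Errera rule (shortest wall
## bisecting the area) or by minimising a weighted potential over the
## central angles of the wall endpoints.

#' Division specification
#'
#' @param model `"errera"` (shortest area-bisecting wall) or
#'   `"potential"` (weighted potential over endpoint angles).
#' @param variable Threshold variable: `"area"` or a species name.
#' @param mean,sd Mean and standard deviation of the normal threshold
#'   distribution (draws are truncated below at 1% of `mean`).
#' @param weights Potential weights `c(wA, wL, we, wg)`: area
#'   equalisation, wall length, perpendicularity to the extension axis,
#'   perpendicularity to the growth axis.
#' @param eps_L,eps_perp Regularisation parameters of the length and
#'   perpendicularity potentials.
#' @return A `division_spec` object.
#' @export
division_spec <- function(model = c("errera", "potential"),
                          variable = "area", mean, sd = 0,
                          weights = c(wA = 1, wL = 1, we = 0, wg = 0),
                          eps_L = 0.1, eps_perp = 0.1) {
  model <- match.arg(model)
  stopifnot(sd >= 0, mean > 0)
  weights <- rep_len(unname(weights), 4L)
  names(weights) <- c("wA", "wL", "we", "wg")
  if (any(weights < 0) || all(weights == 0))
    stop_tessella("weights must be non-negative with at least one positive")
  structure(list(model = model, variable = variable, mean = mean,
                 sd = sd, weights = weights, eps_L = eps_L,
                 eps_perp = eps_perp),
            class = "division_spec")
}

#' Draw a division threshold
#'
#' Normal draw truncated below at 1% of the mean (a clamped draw is
#' reported with a message).
#'
#' @param spec A [division_spec()].
#' @param n Number of draws.
#' @return Numeric vector of thresholds.
#' @export
sample_threshold <- function(spec, n = 1L) {
  x <- stats::rnorm(n, spec$mean, spec$sd)
  floor_v <- 0.01 * spec$mean
  if (any(x < floor_v)) {
    message("sample_threshold: ", sum(x < floor_v),
            " draw(s) clamped to the positive floor")
    x <- pmax(x, floor_v)
  }
  x
}

## Boundary parameterisation ---------------------------------------------
## Arclength parameterisation of a closed polygon boundary, with O(1)
## daughter-area evaluation from cumulative shoelace sums.

boundary_param <- function(P) {
  n <- nrow(P)
  nx <- c(2:n, 1L)
  seg <- P[nx, , drop = FALSE] - P
  len <- sqrt(seg[, 1L]^2 + seg[, 2L]^2)
  cum <- c(0, cumsum(len))        # cum[i] = arclength at vertex i
  crossv <- P[, 1L] * P[nx, 2L] - P[nx, 1L] * P[, 2L]
  ccum <- c(0, cumsum(crossv))    # cumulative shoelace contributions
  list(P = P, n = n, nx = nx, len = len, cum = cum, L = cum[n + 1L],
       ccum = ccum, area = 0.5 * ccum[n + 1L],
       centroid = colMeans(P))
}

## position s in [0, L) -> list(point, seg index, fraction along segment)
param_point <- function(bp, s) {
  s <- s %% bp$L
  i <- findInterval(s, bp$cum, rightmost.closed = TRUE)
  i <- min(max(i, 1L), bp$n)
  f <- (s - bp$cum[i]) / bp$len[i]
  list(pt = bp$P[i, ] + f * (bp$P[bp$nx[i], ] - bp$P[i, ]),
       seg = i, frac = f)
}

cross2 <- function(a, b) a[1L] * b[2L] - a[2L] * b[1L]

## area of the daughter bounded by the boundary arc from s1 to s2
## (forward along the parameterisation) and the chord s2 -> s1
area_between <- function(bp, s1, s2) {
  s1 <- s1 %% bp$L; s2 <- s2 %% bp$L
  p1 <- param_point(bp, s1); p2 <- param_point(bp, s2)
  wrap <- s2 < s1
  i1 <- p1$seg; i2 <- p2$seg
  ## sum of cross(v_j, v_{j+1}) for full segments strictly inside the arc
  full <- if (!wrap) {
    if (i2 > i1) bp$ccum[i2] - bp$ccum[i1 + 1L] else 0
  } else {
    (bp$ccum[bp$n + 1L] - bp$ccum[i1 + 1L]) + bp$ccum[i2]
  }
  ## both endpoints on one segment with s2 ahead: the arc p1 -> p2 plus
  ## the chord back is a zero-area sliver
  tot <- if (!wrap && i1 == i2 && p2$frac >= p1$frac) 0
  else full + cross2(p1$pt, bp$P[bp$nx[i1], ]) +
    cross2(bp$P[i2, ], p2$pt) + cross2(p2$pt, p1$pt)
  0.5 * tot
}

## Wall candidates --------------------------------------------------------

wall_candidate <- function(bp, s1, s2) {
  p1 <- param_point(bp, s1); p2 <- param_point(bp, s2)
  d <- sqrt(sum((p2$pt - p1$pt)^2))
  A1 <- area_between(bp, s1, s2)
  A2 <- bp$area - A1
  cen <- bp$centroid
  ## distance from centroid to the wall segment
  w <- p2$pt - p1$pt
  tt <- if (d > 0) sum((cen - p1$pt) * w) / (d * d) else 0
  tt <- min(max(tt, 0), 1)
  Delta <- sqrt(sum((p1$pt + tt * w - cen)^2))
  th <- function(p) atan2(p[2L] - cen[2L], p[1L] - cen[1L])
  structure(list(s1 = s1, s2 = s2, endpoints = rbind(p1$pt, p2$pt),
                 d = d, Delta = Delta, A1 = A1, A2 = A2,
                 theta1 = th(p1$pt), theta2 = th(p2$pt)),
            class = "wall_candidate")
}

#' @export
print.wall_candidate <- function(x, ...) {
  cat(sprintf("<wall: d=%.4g, areas %.4g/%.4g, offset %.4g>\n",
              x$d, x$A1, x$A2, x$Delta))
  invisible(x)
}

## equal-area partner: the s2 (forward of s1) with area_between = A/2;
## area_between(bp, s1, .) grows monotonically from 0 to A
equal_area_partner <- function(bp, s1) {
  target <- bp$area / 2
  f <- function(s2) area_between(bp, s1, s1 + s2) - target
  lo <- 1e-9 * bp$L; hi <- bp$L * (1 - 1e-9)
  r <- stats::uniroot(f, c(lo, hi), tol = 1e-12 * bp$L)
  (s1 + r$root) %% bp$L
}

#' Errera wall: the shortest area-bisecting chord
#'
#' Scans one endpoint densely along the boundary, solves the equal-area
#' constraint for the partner endpoint by monotone root bracketing,
#' refines the best chord locally, and breaks ties between global minima
#' (symmetric cells) by a uniform random choice.
#'
#' @param cell A k x 2 polygon (counter-clockwise), or a `tissue` with
#'   `ci` given.
#' @param ci Cell index when `cell` is a tissue.
#' @param n_scan Number of scan positions for the first endpoint.
#' @param tie_tol Relative tolerance within which chord lengths count as
#'   tied global minima.
#' @return A `wall_candidate` (endpoints, length `d`, daughter areas
#'   `A1`, `A2`, centroid offset `Delta`, central angles).
#' @examples
#' set.seed(1)
#' sq <- rbind(c(0,0), c(1,0), c(1,1), c(0,1))
#' errera_wall(sq)$d   # 1: a mid-edge chord
#' @export
errera_wall <- function(cell, ci = NULL, n_scan = 240L, tie_tol = 1e-9) {
  P <- if (inherits(cell, "tissue")) cell_polygon(cell, ci) else cell
  bp <- boundary_param(P)
  if (!(bp$area > 0))
    stop_tessella("errera_wall: polygon is not counter-clockwise simple")
  s_grid <- seq(0, bp$L, length.out = n_scan + 1L)[-(n_scan + 1L)]
  dlen <- numeric(n_scan)
  s2s <- numeric(n_scan)
  for (i in seq_len(n_scan)) {
    s2 <- equal_area_partner(bp, s_grid[i])
    s2s[i] <- s2
    p1 <- param_point(bp, s_grid[i])$pt
    p2 <- param_point(bp, s2)$pt
    dlen[i] <- sqrt(sum((p2 - p1)^2))
  }
  ## local refinement around each grid minimum candidate
  refine <- function(s0) {
    h <- bp$L / n_scan
    obj <- function(s1) {
      s2 <- equal_area_partner(bp, s1)
      p1 <- param_point(bp, s1)$pt; p2 <- param_point(bp, s2)$pt
      sqrt(sum((p2 - p1)^2))
    }
    op <- stats::optimize(obj, c(s0 - h, s0 + h), tol = 1e-10 * bp$L)
    op
  }
  ## refine only local grid minima near the global one (flat tie sets on
  ## symmetric cells are capped; refinement barely moves them anyway)
  best_global <- min(dlen)
  prv <- c(n_scan, seq_len(n_scan - 1L)); nxtv <- c(2:n_scan, 1L)
  is_locmin <- dlen <= dlen[prv] & dlen <= dlen[nxtv]
  cand_idx <- which(is_locmin & dlen <= best_global * (1 + 1e-3))
  if (!length(cand_idx)) cand_idx <- which.min(dlen)
  if (length(cand_idx) > 16L)
    cand_idx <- cand_idx[round(seq(1L, length(cand_idx), length.out = 16L))]
  refined <- lapply(s_grid[cand_idx], refine)
  objs <- vapply(refined, `[[`, numeric(1), "objective")
  mins <- vapply(refined, `[[`, numeric(1), "minimum")
  dbest <- min(objs)
  ties <- which(objs <= dbest * (1 + max(tie_tol, 1e-12)))
  ## deduplicate ties that refined to (nearly) the same chord
  keep <- ties[!duplicated(round(mins[ties] / (1e-6 * bp$L)))]
  pick <- if (length(keep) > 1L) keep[sample.int(length(keep), 1L)]
          else keep[1L]
  s1 <- mins[pick] %% bp$L
  wall_candidate(bp, s1, equal_area_partner(bp, s1))
}

## Principal axes ---------------------------------------------------------

principal_axis <- function(X, tol = 1e-8) {
  X <- sweep(X, 2L, colMeans(X))
  M <- crossprod(X) / (nrow(X) - 1L)
  ev <- eigen(M, symmetric = TRUE)
  degenerate <- (ev$values[1L] - ev$values[2L]) <=
    tol * max(ev$values[1L], 1e-300)
  v <- ev$vectors[, 1L]
  if (v[1L] < 0 || (v[1L] == 0 && v[2L] < 0)) v <- -v
  structure(v, degenerate = degenerate)
}

#' Principal axes of cell shape and growth
#'
#' `extension_axis` returns the unit eigenvector of the larger eigenvalue
#' of the covariance matrix of the (centred) cell vertex coordinates —
#' the direction of maximal cell extension.  `growth_axis` applies the
#' same construction to the vertex velocities — the direction of
#' instantaneous maximal growth.  The sign is normalised to non-negative
#' x component.  For isotropic cells (equal eigenvalues) the result
#' carries `attr(., "degenerate") = TRUE`.
#'
#' @param vertices k x 2 matrix of cell vertex coordinates.
#' @param velocities k x 2 matrix of those vertices' velocities.
#' @return Unit 2-vector with a `degenerate` attribute.
#' @export
extension_axis <- function(vertices) {
  stopifnot(nrow(vertices) >= 3L)
  principal_axis(vertices)
}

#' @rdname extension_axis
#' @export
growth_axis <- function(velocities) {
  stopifnot(nrow(velocities) >= 3L)
  principal_axis(velocities)
}

#' Potential-model components of a candidate wall
#'
#' \eqn{V_A = ((A_1-A_2)/A)^2};
#' \eqn{V_L = ((d-d_{min})^2 + \epsilon_L \Delta^2)/(d+d_{min})^2} with
#' \eqn{d_{min}} the shortest chord through the cell center and
#' \eqn{\Delta} the wall's distance from the center;
#' \eqn{V_\perp(v) = v\cdot W + \epsilon_\perp \Delta/d} with `W` the unit
#' vector along the wall, giving \eqn{V_e = V_\perp(e)} and
#' \eqn{V_g = V_\perp(g)} for the extension and growth axes.
#'
#' @param cell k x 2 cell polygon (counter-clockwise).
#' @param candidate A `wall_candidate`.
#' @param spec A [division_spec()] (for `eps_L`, `eps_perp`).
#' @param velocities Optional k x 2 vertex velocities (needed for `V_g`).
#' @param d_min Precomputed shortest center chord (computed if `NULL`).
#' @return Named vector `c(V_A, V_L, V_e, V_g)`; components whose axis is
#'   degenerate (or unavailable) are `NA`.
#' @export
potential_components <- function(cell, candidate, spec,
                                 velocities = NULL, d_min = NULL) {
  if (candidate$d <= 0)
    stop_tessella("degenerate candidate wall (d = 0)")
  bp <- boundary_param(cell)
  d_min <- d_min %||% min_center_chord(bp)
  V_A <- ((candidate$A1 - candidate$A2) / bp$area)^2
  V_L <- ((candidate$d - d_min)^2 + spec$eps_L * candidate$Delta^2) /
    (candidate$d + d_min)^2
  W <- (candidate$endpoints[2L, ] - candidate$endpoints[1L, ]) / candidate$d
  vperp <- function(v) sum(v * W) + spec$eps_perp * candidate$Delta / candidate$d
  e <- extension_axis(cell)
  V_e <- if (attr(e, "degenerate")) NA_real_ else vperp(e)
  V_g <- if (is.null(velocities)) NA_real_ else {
    gax <- growth_axis(velocities)
    if (attr(gax, "degenerate")) NA_real_ else vperp(gax)
  }
  c(V_A = V_A, V_L = V_L, V_e = V_e, V_g = V_g)
}

## shortest chord through the cell center (centroid): scan directions
min_center_chord <- function(bp, n_dir = 90L) {
  cen <- bp$centroid
  th <- seq(0, pi, length.out = n_dir + 1L)[-(n_dir + 1L)]
  best <- Inf
  for (a in th) {
    u <- c(cos(a), sin(a))
    tpos <- ray_hit(bp, cen, u)
    tneg <- ray_hit(bp, cen, -u)
    if (is.finite(tpos$t) && is.finite(tneg$t))
      best <- min(best, tpos$t + tneg$t)
  }
  best
}

## first intersection of the ray cen + t*u (t > 0) with the boundary
ray_hit <- function(bp, cen, u) {
  P <- bp$P; n <- bp$n; nx <- bp$nx
  best_t <- Inf; best_s <- NA_real_; best_pt <- NULL
  for (i in seq_len(n)) {
    a <- P[i, ]; b <- P[nx[i], ]
    e <- b - a
    den <- u[1L] * (-e[2L]) - u[2L] * (-e[1L])
    if (abs(den) < 1e-14) next
    rhs <- a - cen
    tt <- (rhs[1L] * (-e[2L]) - rhs[2L] * (-e[1L])) / den
    ss <- (u[1L] * rhs[2L] - u[2L] * rhs[1L]) / den
    if (tt > 1e-12 && ss >= -1e-12 && ss <= 1 + 1e-12 && tt < best_t) {
      best_t <- tt
      best_s <- (bp$cum[i] + min(max(ss, 0), 1) * bp$len[i]) %% bp$L
      best_pt <- cen + tt * u
    }
  }
  list(t = best_t, s = best_s, pt = best_pt)
}

## candidate wall from central angles (rays from centroid)
candidate_from_angles <- function(bp, theta1, theta2) {
  h1 <- ray_hit(bp, bp$centroid, c(cos(theta1), sin(theta1)))
  h2 <- ray_hit(bp, bp$centroid, c(cos(theta2), sin(theta2)))
  if (!is.finite(h1$t) || !is.finite(h2$t)) return(NULL)
  if (abs((h1$s - h2$s) %% bp$L) < 1e-12 * bp$L) return(NULL)
  wall_candidate(bp, h1$s, h2$s)
}

#' Potential-model wall placement
#'
#' Minimises \eqn{V(\theta_1, \theta_2) = \sum_i w_i V_i} over the
#' central angles of the wall endpoints: a coarse angular grid followed by
#' Nelder-Mead refinement.  Components with degenerate axes (symmetric
#' cells, isotropic growth) are dropped for the division with a warning;
#' ties between equivalent global minima are broken uniformly at random.
#'
#' @param cell k x 2 cell polygon (counter-clockwise), or a `tissue` with
#'   `ci`.
#' @param spec A [division_spec()] with `model = "potential"`.
#' @param velocities Optional vertex velocities of the cell polygon (for
#'   the growth-axis component).
#' @param ci Cell index when `cell` is a tissue.
#' @param grid_n Angular grid resolution per axis.
#' @return A `wall_candidate`.
#' @export
potential_wall <- function(cell, spec, velocities = NULL, ci = NULL,
                           grid_n = 64L) {
  P <- if (inherits(cell, "tissue")) cell_polygon(cell, ci) else cell
  bp <- boundary_param(P)
  w <- spec$weights
  e_ax <- extension_axis(P)
  g_ax <- if (!is.null(velocities)) growth_axis(velocities)
  dropped <- character(0)
  if (w[["we"]] > 0 && attr(e_ax, "degenerate")) {
    dropped <- c(dropped, "V_e"); w[["we"]] <- 0
  }
  if (w[["wg"]] > 0 && (is.null(g_ax) || attr(g_ax, "degenerate"))) {
    dropped <- c(dropped, "V_g"); w[["wg"]] <- 0
  }
  if (length(dropped))
    warning("potential_wall: dropping degenerate component(s) ",
            paste(dropped, collapse = ", "), call. = FALSE)
  if (all(w == 0))
    stop_tessella("all potential components degenerate; division aborted")
  d_min <- min_center_chord(bp)
  Vfun <- function(th1, th2) {
    cand <- candidate_from_angles(bp, th1, th2)
    if (is.null(cand) || cand$d <= 1e-12) return(Inf)
    val <- 0
    if (w[["wA"]] > 0)
      val <- val + w[["wA"]] * ((cand$A1 - cand$A2) / bp$area)^2
    if (w[["wL"]] > 0)
      val <- val + w[["wL"]] *
        ((cand$d - d_min)^2 + spec$eps_L * cand$Delta^2) /
        (cand$d + d_min)^2
    if (w[["we"]] > 0 || w[["wg"]] > 0) {
      W <- (cand$endpoints[2L, ] - cand$endpoints[1L, ]) / cand$d
      pen <- spec$eps_perp * cand$Delta / cand$d
      ## a wall is orientation-free: score it by its worse W orientation
      ## (|v.W|), so perpendicular walls (0) beat parallel ones (1) and
      ## the anti-parallel orientation (-1) cannot win spuriously
      if (w[["we"]] > 0) val <- val + w[["we"]] * (abs(sum(e_ax * W)) + pen)
      if (w[["wg"]] > 0) val <- val + w[["wg"]] * (abs(sum(g_ax * W)) + pen)
    }
    val
  }
  th <- seq(0, 2 * pi, length.out = grid_n + 1L)[-(grid_n + 1L)]
  vals <- matrix(Inf, grid_n, grid_n)
  for (i in seq_len(grid_n)) for (j in seq_len(grid_n)) {
    if (i == j) next
    vals[i, j] <- Vfun(th[i], th[j])
  }
  if (!any(is.finite(vals)))
    stop_tessella("no valid candidate wall found; division aborted")
  vbest <- min(vals)
  ties <- which(vals <= vbest + max(1e-9, 1e-9 * abs(vbest)), arr.ind = TRUE)
  pick <- ties[sample.int(nrow(ties), 1L), ]
  op <- stats::optim(c(th[pick[1L]], th[pick[2L]]),
                     function(p) Vfun(p[1L], p[2L]),
                     method = "Nelder-Mead",
                     control = list(reltol = 1e-12, maxit = 400L))
  cand <- candidate_from_angles(bp, op$par[1L], op$par[2L])
  if (is.null(cand))
    cand <- candidate_from_angles(bp, th[pick[1L]], th[pick[2L]])
  cand
}

## Mesh surgery -----------------------------------------------------------

## chain an unordered edge set (forming one cycle) into cyclic order
order_edge_loop <- function(E, eids) {
  k <- length(eids)
  vmap <- new.env(hash = TRUE, parent = emptyenv())
  for (e in eids) {
    for (v in E[e, ]) {
      key <- as.character(v)
      vmap[[key]] <- c(vmap[[key]], e)
    }
  }
  out <- integer(k)
  out[1L] <- eids[1L]
  cur_v <- E[eids[1L], 2L]
  for (i in 2:k) {
    cand <- vmap[[as.character(cur_v)]]
    nxt <- setdiff(cand, out[seq_len(i - 1L)])
    if (length(nxt) != 1L)
      stop_tessella("edge set does not form a single cycle")
    out[i] <- nxt
    cur_v <- setdiff(E[nxt, ], cur_v)
    if (length(cur_v) != 1L)
      stop_tessella("edge set does not form a single cycle")
  }
  out
}

#' Divide a cell along a wall candidate
#'
#' Performs the mesh surgery: the wall endpoints are inserted as new
#' vertices (splitting the boundary edges they land on, with the
#' neighbouring cell's edge loop updated too; endpoints within `snap_tol`
#' of an existing vertex snap to it), the new straight wall edge is
#' added, and the mother cell is replaced by two daughters.  Daughters
#' inherit the mother's concentrations unchanged (amounts proportional to
#' area); the new wall's rest length is its current length; split edges
#' partition their rest length proportionally; each daughter draws a
#' fresh threshold when a `division_spec` is supplied.
#'
#' @param t A `tissue`.
#' @param ci Index of the dividing cell.
#' @param wall A `wall_candidate` on that cell's boundary (from
#'   [errera_wall()] or [potential_wall()]).
#' @param state Optional simulation state list with any of: `conc`
#'   (cells x species matrix), `delta` (per-edge rest lengths),
#'   `thresholds` (per-cell), `spec` (a [division_spec()]), `ids`
#'   (persistent cell ids), `next_id`, `time`.
#' @param snap_tol Relative tolerance for snapping endpoints to existing
#'   vertices.
#' @return List: `tissue` (updated), `state` (updated), `daughters` (the
#'   two cell indices: mother's index and the appended one), `lineage`
#'   (one-row data frame record), or `NULL` if the division would create
#'   a zero-area daughter (a warning is raised and nothing is changed).
#' @export
divide_cell <- function(t, ci, wall, state = list(), snap_tol = 1e-6) {
  A <- abs(signed_area(cell_polygon(t, ci)))
  if (min(wall$A1, wall$A2) < 1e-9 * A) {
    warning("divide_cell: zero-area daughter; division aborted",
            call. = FALSE)
    return(NULL)
  }
  loop <- cell_loop_vertices(t, ci)
  P <- t$V[loop, , drop = FALSE]
  bp <- boundary_param(P)
  V <- t$V; E <- t$E; C <- t$C
  delta <- state$delta
  neighbours_of <- function(eid) {
    which(vapply(C, function(ed) eid %in% ed, logical(1)))
  }
  insert_endpoint <- function(s) {
    p <- param_point(bp, s)
    seg_len <- bp$len[p$seg]
    if (p$frac * seg_len < snap_tol * seg_len)
      return(list(v = loop[p$seg]))
    if ((1 - p$frac) * seg_len < snap_tol * seg_len)
      return(list(v = loop[bp$nx[p$seg]]))
    ## split the edge under this boundary segment
    eid <- C[[ci]][p$seg]
    a <- loop[p$seg]; b <- loop[bp$nx[p$seg]]
    V <<- rbind(V, p$pt)
    nv <- nrow(V)
    E[eid, ] <<- c(a, nv)
    E <<- rbind(E, c(nv, b))
    ne <- nrow(E)
    if (!is.null(delta)) {
      dl <- delta[eid]
      delta[eid] <<- dl * p$frac
      delta <<- c(delta, dl * (1 - p$frac))
    }
    for (cc in neighbours_of(eid)) {
      C[[cc]] <<- order_edge_loop(E, c(C[[cc]], ne))
    }
    ## re-derive the mother's vertex loop; order_edge_loop's direction is
    ## arbitrary, so restore CCW to keep loop/edge positions aligned
    tmp <- list(V = V, E = E, C = C)
    loop2 <- cell_loop_vertices(tmp, ci)
    if (signed_area(V[loop2, , drop = FALSE]) < 0) {
      C[[ci]] <<- rev(C[[ci]])
      tmp$C <- C
      loop2 <- cell_loop_vertices(tmp, ci)
    }
    loop <<- loop2
    bp <<- boundary_param(V[loop, , drop = FALSE])
    list(v = nv)
  }
  ep1 <- insert_endpoint(wall$s1)
  ## s-position of endpoint 2 must be re-located on the updated boundary:
  ## use nearest boundary point of the stored coordinates
  s2 <- nearest_boundary_s(bp, wall$endpoints[2L, ])
  ep2 <- insert_endpoint(s2)
  va <- ep1$v; vb <- ep2$v
  if (va == vb) {
    warning("divide_cell: wall endpoints coincide; division aborted",
            call. = FALSE)
    return(NULL)
  }
  ## new wall edge
  E <- rbind(E, c(va, vb))
  wall_eid <- nrow(E)
  if (!is.null(delta))
    delta <- c(delta, sqrt(sum((V[va, ] - V[vb, ])^2)))
  ## split the mother's boundary cycle at va, vb
  ed <- C[[ci]]
  k <- length(ed)
  pa <- match(va, loop); pb <- match(vb, loop)
  if (is.na(pa) || is.na(pb))
    stop_tessella("internal: wall endpoints not on mother boundary")
  if (pa > pb) { tmp <- pa; pa <- pb; pb <- tmp }
  arc1 <- ed[pa:(pb - 1L)]
  arc2 <- ed[c(seq_len(pa - 1L), if (pb <= k) pb:k)]
  d1 <- order_edge_loop(E, c(arc1, wall_eid))
  d2 <- order_edge_loop(E, c(arc2, wall_eid))
  C[[ci]] <- d1
  C[[length(C) + 1L]] <- d2
  t2 <- tissue(V, E, C, validate = FALSE)
  daughters <- c(ci, length(C))
  ## state updates
  st <- state
  st$delta <- delta
  if (!is.null(st$conc)) {
    st$conc <- rbind(st$conc, st$conc[ci, , drop = FALSE])
    rownames(st$conc) <- NULL
  }
  if (!is.null(st$fixed_mask))
    st$fixed_mask <- rbind(st$fixed_mask, st$fixed_mask[ci, , drop = FALSE])
  thr <- c(NA_real_, NA_real_)
  if (!is.null(st$spec)) thr <- sample_threshold(st$spec, 2L)
  if (!is.null(st$thresholds)) {
    st$thresholds[ci] <- thr[1L]
    st$thresholds <- c(st$thresholds, thr[2L])
  }
  parent_id <- ci; d_ids <- daughters
  if (!is.null(st$ids)) {
    parent_id <- st$ids[ci]
    nid <- st$next_id %||% (max(st$ids) + 1L)
    d_ids <- c(nid, nid + 1L)
    st$ids[ci] <- nid
    st$ids <- c(st$ids, nid + 1L)
    st$next_id <- nid + 2L
  }
  lineage <- data.frame(
    parent = parent_id, daughter1 = d_ids[1L], daughter2 = d_ids[2L],
    time = state$time %||% NA_real_,
    x1 = V[va, 1L], y1 = V[va, 2L], x2 = V[vb, 1L], y2 = V[vb, 2L],
    threshold1 = thr[1L], threshold2 = thr[2L])
  list(tissue = t2, state = st, daughters = daughters, lineage = lineage)
}

nearest_boundary_s <- function(bp, pt) {
  best <- Inf; bs <- 0
  for (i in seq_len(bp$n)) {
    a <- bp$P[i, ]; b <- bp$P[bp$nx[i], ]
    w <- b - a
    tt <- sum((pt - a) * w) / sum(w * w)
    tt <- min(max(tt, 0), 1)
    q <- a + tt * w
    d2 <- sum((pt - q)^2)
    if (d2 < best) { best <- d2; bs <- bp$cum[i] + tt * bp$len[i] }
  }
  bs %% bp$L
}
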