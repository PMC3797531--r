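test_that("threshold draws are normal with a positive floor", {
  spec0 <- division_spec("errera", mean = 2, sd = 0)
  expect_equal(sample_threshold(spec0, 5), rep(2, 5))
  set.seed(10)
  spec <- division_spec("errera", mean = 2, sd = 0.3)
  x <- sample_threshold(spec, 1e5)
  expect_lt(abs(mean(x) - 2), 3 * 0.3 / sqrt(1e5))
  ## pathological sd: draws clamp at 1% of the mean, with a message
  specw <- division_spec("errera", mean = 1, sd = 50)
  expect_message(y <- sample_threshold(specw, 200), "clamped")
  expect_true(all(y >= 0.01))
})

test_that("errera wall on rectangles is the shortest area-bisecting chord", {
  set.seed(2)
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  w <- errera_wall(sq)
  expect_equal(w$d, 1, tolerance = 1e-6)
  ## endpoints at mid-edges of opposite sides
  mids <- w$endpoints[, 1] + w$endpoints[, 2]
  expect_true(all(abs(w$endpoints - 0.5) %in% c(0.5, 0) |
                  abs(w$endpoints - 0.5) < 1e-6))
  expect_equal(w$A1, 0.5, tolerance = 1e-6)
  ## the square has two equivalent walls; both occur across seeds
  dirs <- replicate(20, {
    wi <- errera_wall(sq)
    if (abs(wi$endpoints[1, 1] - wi$endpoints[2, 1]) < 1e-3) "v" else "h"
  })
  expect_setequal(unique(dirs), c("v", "h"))

  r21 <- rbind(c(0, 0), c(2, 0), c(2, 1), c(0, 1))
  w2 <- errera_wall(r21)
  expect_equal(w2$d, 1, tolerance = 1e-6)
  expect_equal(sort(w2$endpoints[, 1]), c(1, 1), tolerance = 1e-6)
  expect_equal(w2$A1, w2$A2, tolerance = 1e-6)
})

test_that("errera matches the brute-force bisecting-chord oracle", {
  set.seed(11)
  for (i in 1:6) {
    P <- random_convex_polygon(n = sample(5:9, 1))
    w <- errera_wall(P)
    oracle <- errera_oracle_scan(P, res = 1e-3)
    expect_lte(w$d, oracle + 1e-3)
    A <- abs(tessella:::signed_area(P))
    expect_lt(abs(w$A1 - A / 2) / A, 1e-6)
  }
})

test_that("potential components match their defining formulas", {
  spec <- division_spec("potential", mean = 1, weights = c(1, 1, 1, 1),
                        eps_L = 0.1, eps_perp = 0.1)
  r21 <- rbind(c(0, 0), c(2, 0), c(2, 1), c(0, 1))
  set.seed(1)
  w <- errera_wall(r21)          # the short midline through the center
  vc <- potential_components(r21, w, spec)
  expect_equal(vc[["V_A"]], 0, tolerance = 1e-10)
  expect_equal(vc[["V_L"]], 0, tolerance = 1e-8)   # d = d_min, Delta = 0
  ## midline is vertical, extension axis horizontal: raw dot = 0
  expect_equal(vc[["V_e"]], 0, tolerance = 1e-8)
  expect_true(is.na(vc[["V_g"]]))                  # no velocities given

  ## wall through the center parallel to the extension axis: |dot| = 1
  bp <- tessella:::boundary_param(r21)
  horiz <- tessella:::wall_candidate(bp, tessella:::nearest_boundary_s(bp, c(0, 0.5)),
                                     tessella:::nearest_boundary_s(bp, c(2, 0.5)))
  vch <- potential_components(r21, horiz, spec)
  expect_equal(abs(vch[["V_e"]]), 1, tolerance = 1e-8)
})

test_that("extension and growth axes are principal covariance eigenvectors", {
  r41 <- rbind(c(0, 0), c(4, 0), c(4, 1), c(0, 1))
  e <- extension_axis(r41)
  expect_equal(abs(as.numeric(e)), c(1, 0), tolerance = 1e-12)
  expect_false(attr(e, "degenerate"))
  ## regular hexagon is isotropic
  hexP <- cbind(cos(pi / 6 + (0:5) * pi / 3), sin(pi / 6 + (0:5) * pi / 3))
  expect_true(attr(extension_axis(hexP), "degenerate"))
  ## uniform dilation velocity field is isotropic too
  vel <- sweep(hexP, 2, colMeans(hexP)) * 0.3
  expect_true(attr(growth_axis(vel), "degenerate"))
})

test_that("potential wall placement minimises the weighted sum", {
  set.seed(3)
  r21 <- rbind(c(0, 0), c(2, 0), c(2, 1), c(0, 1))
  spec <- division_spec("potential", mean = 1, weights = c(1, 1, 0, 0))
  w <- potential_wall(r21, spec)
  expect_equal(w$d, 1, tolerance = 1e-3)
  expect_equal(w$A1, w$A2, tolerance = 1e-2)

  ## perpendicularity-only on an elongated cell: wall crosses the long axis
  r41 <- rbind(c(0, 0), c(4, 0), c(4, 1), c(0, 1))
  spec_e <- division_spec("potential", mean = 1, weights = c(0, 0, 1, 0))
  we <- potential_wall(r41, spec_e)
  Wv <- (we$endpoints[2, ] - we$endpoints[1, ]) / we$d
  expect_lt(abs(Wv[1]), 1e-2)    # wall direction ~ vertical (perp to x)

  ## area-only with random tie-break still bisects
  spec_a <- division_spec("potential", mean = 1, weights = c(1, 0, 0, 0))
  wa <- potential_wall(r21, spec_a)
  expect_equal(wa$A1, wa$A2, tolerance = 1e-2)

  ## degenerate axis components are dropped with a warning
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_warning(potential_wall(sq, division_spec("potential", mean = 1,
                                                  weights = c(1, 0, 1, 0))),
                 "degenerate")
})

test_that("potential model with (wA, wL) recovers the Errera wall", {
  set.seed(4)
  for (i in 1:4) {
    P <- random_convex_polygon(n = 7)
    we <- errera_wall(P)
    spec <- division_spec("potential", mean = 1, weights = c(1, 1, 0, 0),
                          eps_L = 1e-6)
    wp <- potential_wall(P, spec)
    expect_equal(wp$d, we$d, tolerance = 0.05)
  }
})

test_that("divide_cell performs valid surgery and conserves everything", {
  set.seed(5)
  sq <- unit_square_tissue()
  w <- errera_wall(cell_polygon(sq, 1))
  st <- list(conc = matrix(3, 1, 1, dimnames = list(NULL, "X")),
             delta = compute_geometry(sq)$edge_len, time = 1,
             ids = 1L, next_id = 2L,
             spec = division_spec("errera", mean = 1, sd = 0))
  res <- divide_cell(sq, 1, w, st)
  g2 <- compute_geometry(res$tissue)
  expect_equal(sum(g2$area), 1, tolerance = 1e-9)
  expect_equal(res$state$conc[, "X"], c(3, 3))      # concentrations copied
  ## amounts proportional to daughter areas
  expect_equal(sum(res$state$conc[, "X"] * g2$area), 3, tolerance = 1e-9)
  expect_equal(res$lineage$parent, 1)
  expect_setequal(c(res$lineage$daughter1, res$lineage$daughter2), c(2, 3))
  ## new wall rest length equals its current length
  expect_equal(res$state$delta[nrow(res$tissue$E)],
               g2$edge_len[nrow(res$tissue$E)])

  ## neighbour of a split edge gains exactly one vertex and stays valid
  t2 <- two_square_tissue()
  wl <- errera_wall(cell_polygon(t2, 1))
  n_before <- length(tessella:::cell_loop_vertices(t2, 2))
  res2 <- divide_cell(t2, 1, wl,
                      list(delta = compute_geometry(t2)$edge_len))
  expect_silent(validate_tissue(res2$tissue))
  n_after <- length(tessella:::cell_loop_vertices(res2$tissue, 2))
  ## the horizontal mid-wall splits both shared-side neighbours of cell 1;
  ## cell 2 gains a vertex only if its shared edge was split
  expect_true(n_after %in% c(n_before, n_before + 1L))
})

test_that("random divisions preserve area, amounts, and mesh validity", {
  set.seed(12)
  t0 <- random_tissue(10, seed = 31)
  g0 <- compute_geometry(t0)
  conc <- matrix(runif(n_cells(t0) * 2, 0.5, 2), ncol = 2,
                 dimnames = list(NULL, c("X", "Y")))
  st <- list(conc = conc, delta = g0$edge_len)
  A0 <- sum(g0$area)
  M0 <- colSums(conc * g0$area)
  tt <- t0
  for (k in 1:25) {
    ci <- sample(n_cells(tt), 1)
    w <- errera_wall(cell_polygon(tt, ci))
    res <- divide_cell(tt, ci, w, st)
    if (is.null(res)) next
    tt <- res$tissue; st <- res$state
    g <- compute_geometry(tt)
    expect_silent(validate_tissue(tt))
    expect_lt(abs(sum(g$area) - A0) / A0, 1e-9)
    M <- colSums(st$conc * g$area)
    expect_lt(max(abs(M - M0) / M0), 1e-9)
  }
  expect_equal(n_cells(tt), 35L)
})
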