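test_that("a resting square with no pressure does not move", {
  sq <- unit_square_tissue()
  g <- compute_geometry(sq)
  m <- mech_state(sq, g, k = 1, P = 0)
  v <- vertex_velocities(sq, g, m)
  expect_equal(v, matrix(0, 4, 2))
})

test_that("extended springs pull their endpoints together", {
  sq <- unit_square_tissue()
  g <- compute_geometry(sq)
  ## all rest lengths at half the current length: contraction toward center
  m <- mech_state(sq, g, delta = rep(0.5, 4), k = 1, P = 0)
  v <- vertex_velocities(sq, g, m)
  ctr <- c(0.5, 0.5)
  for (i in 1:4)
    expect_gt(sum(v[i, ] * (ctr - sq$V[i, ])), 0)
})

test_that("pressure pushes square vertices radially outward at P*s/sqrt(2)", {
  s <- 2
  sq <- unit_square_tissue(s)
  g <- compute_geometry(sq)
  m <- mech_state(sq, g, k = 1, P = 0.3)   # delta = current: springs silent
  v <- vertex_velocities(sq, g, m)
  ctr <- c(s / 2, s / 2)
  for (i in 1:4) {
    speed <- sqrt(sum(v[i, ]^2))
    expect_equal(speed, 0.3 * s / sqrt(2), tolerance = 1e-12)
    dir <- (sq$V[i, ] - ctr) / sqrt(sum((sq$V[i, ] - ctr)^2))
    expect_equal(v[i, ] / speed, dir, tolerance = 1e-12)
  }
})

test_that("rest lengths grow only under extension", {
  expect_equal(theta_ramp(c(2, -1, 0)), c(2, 0, 0))
  sq <- unit_square_tissue(1.5)
  g <- compute_geometry(sq)
  m <- mech_state(sq, g, delta = rep(1, 4), mu = 0.1)
  expect_equal(rest_length_rates(m, g), rep(0.1 * 0.5, 4))
  mc <- mech_state(sq, g, delta = rep(2, 4), mu = 0.1)  # compressed
  expect_equal(rest_length_rates(mc, g), rep(0, 4))
  m0 <- mech_state(sq, g, delta = rep(1, 4), mu = 0)
  expect_equal(rest_length_rates(m0, g), rep(0, 4))
})

test_that("dilution follows -X dA/A under the shoelace area derivative", {
  sq <- unit_square_tissue()
  g <- compute_geometry(sq)
  ## uniform expansion about the center: s(t) = 1 + t at t = 0
  ctr <- c(0.5, 0.5)
  vel <- sweep(sq$V, 2, ctr)           # each vertex at speed |u| outward
  expect_equal(cell_area_rate(sq, g, vel), 2)
  ts <- dilution_terms("X", sq, g, vel)
  C <- matrix(1, 1, 1, dimnames = list(NULL, "X"))
  expect_equal(unname(eval_terms(ts, C, ctx = list())[, "X"]), -2)
  ## zero velocities: zero dilution
  expect_equal(unname(eval_terms(dilution_terms("X", sq, g, vel * 0), C,
                                 ctx = list())[, "X"]), 0)
})

test_that("growth at fixed molecule count halves concentration as area doubles", {
  sq <- unit_square_tissue()
  m <- model_spec(species = list(X = list(init = 1)),
                  grow = grow_arrow(pressure = 1, growth_rate = 0,
                                    spring = 1))
  tr <- run_growing(m, sq, 60, seed = 1, save_at = c(0, 60))
  gf <- compute_geometry(tr$final$tissue)
  ## amount = conc * area is invariant
  expect_equal(unname(tr$final$conc[1, "X"] * gf$area), 1, tolerance = 1e-4)
})

test_that("square-cell closed form: equilibrium perimeter and bounds", {
  cf <- square_cell_closed_form(k = 1, P = 1, Delta = 4)
  expect_true(cf$bounded)
  expect_equal(cf$L_star, 8)
  expect_equal(cf$rate(8), 0)
  ## P = 0: springs relax to the rest perimeter
  expect_equal(square_cell_closed_form(1, 0, 4)$L_star, 4)
  ## P >= 2k: no finite equilibrium
  cf2 <- square_cell_closed_form(k = 1, P = 2, Delta = 4)
  expect_false(cf2$bounded)
  expect_equal(cf2$L_star, Inf)
})

test_that("with P=0 and mu=0 the spring energy is non-increasing", {
  set.seed(6)
  sq <- unit_square_tissue()
  ## perturb vertices, springs at delta = 1
  sq$V <- sq$V + matrix(runif(8, -0.2, 0.2), 4, 2)
  m <- model_spec(species = list(X = list(init = 0)),
                  grow = grow_arrow(pressure = 0, growth_rate = 0,
                                    spring = 1))
  tr <- run_growing(m, sq, 5, seed = 1, save_at = seq(0, 5, 0.5))
  energy <- sapply(tr$snapshots, function(s) {
    g <- compute_geometry(s$tissue)
    sum(0.5 * (1 - g$edge_len)^2)
  })
  expect_true(all(diff(energy) < 1e-8))
})

test_that("constituent-dependent spring/pressure/growth callables resolve", {
  t2 <- two_square_tissue()
  g2 <- compute_geometry(t2)
  C <- matrix(c(1, 3), 2, 1, dimnames = list(NULL, "W"))
  P <- pressure_feedback("W", 0.001, 0.004)
  expect_equal(P(list(C = C)), c(0.005, 0.013))
  mu <- growth_feedback("W", 5e-6, 0.004)
  mur <- mu(g2$edge_cells[, 1], g2$edge_cells[, 2], seq_len(nrow(t2$E)), C)
  shared <- which(!g2$boundary_edge)
  expect_equal(mur[shared], 5e-6 + 0.004 * 4)   # W_p + W_q = 1 + 3
  bnd <- which(g2$boundary_edge & g2$edge_cells[, 1] == 1)[1]
  expect_equal(mur[bnd], 5e-6 + 0.004 * 2)      # boundary doubles own W
})
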