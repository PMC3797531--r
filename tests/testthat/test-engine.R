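test_that("compilation replicates reactions per cell and sizes the state", {
  h <- hex_template(2)
  m <- brusselator_model(perturb = 0)
  sys <- compile_model(m, h, static = TRUE)
  C0 <- init_conc(m, h, sys$geom)
  expect_length(sys$pack(C0), 2 * 19)          # 2 species x 19 cells

  mg <- model_spec(species = list(X = list(init = 1)),
                   grow = grow_arrow(pressure = 0.1, spring = 1))
  sysg <- compile_model(mg, h)
  y <- sysg$pack(matrix(1, 19, 1, dimnames = list(NULL, "X")), h$V,
                 sysg$mech$delta)
  expect_length(y, 19 + 2 * nrow(h$V) + nrow(h$E))

  expect_error(compile_model(mg, h, static = TRUE), "static")
})

test_that("fixed species hold their value but still drive neighbours", {
  t2 <- two_square_tissue()
  m <- model_spec(
    intercellular = list(diffusion_arrow("Y", PI = 1)),
    species = list(Y = list(init = function(t, g) c(1, 0),
                            fixed = function(t, g) c(TRUE, FALSE))))
  tr <- run_static(m, t2, 50)
  yf <- tr$final$conc[, "Y"]
  expect_equal(unname(yf[1]), 1)                        # Dirichlet cell pinned
  expect_equal(unname(yf[2]), 1, tolerance = 1e-5)      # neighbour equilibrates up
})

test_that("static runs reproduce closed-form kinetics", {
  sq <- unit_square_tissue()
  ## no reactions: state constant
  m0 <- model_spec(species = list(X = list(init = 0.7)))
  tr0 <- run_static(m0, sq, 5)
  expect_equal(unname(tr0$final$conc[1, "X"]), 0.7)
  ## A <-> B with k1 = k2 = 1 from (1, 0): A(t) = 1/2 (1 + e^{-2t})
  m1 <- model_spec(reactions = parse_arrow("A <-> B", list(1, 1)),
                   species = list(A = list(init = 1), B = list(init = 0)))
  tr1 <- run_static(m1, sq, 3, save_at = c(0, 1, 3))
  expect_equal(unname(conc_at(tr1, 1)[1, "A"]), 0.5 * (1 + exp(-2)),
               tolerance = 1e-6)
  expect_equal(unname(tr1$final$conc[1, "A"] + tr1$final$conc[1, "B"]), 1,
               tolerance = 1e-9)
})

test_that("a single growing square divides exactly once at its threshold", {
  sq <- unit_square_tissue()
  ## equilibrium perimeter 8 -> area 4; threshold below that crosses once,
  ## daughters (area ~2 with fresh thresholds ~3) never cross again
  m <- model_spec(species = list(X = list(init = 1)),
                  grow = grow_arrow(pressure = 1, growth_rate = 0,
                                    spring = 1),
                  divide = division_spec("errera", mean = 3, sd = 0))
  tr <- run_growing(m, sq, 40, seed = 3, save_at = c(0, 40),
                    stop_after_divisions = 1)
  expect_equal(n_cells(tr$final$tissue), 2L)
  expect_equal(nrow(tr$lineage), 1L)

  ## division time oracle: integrate the square-cell closed form
  ## dL/dt = L (P - 2k) + 2 k Delta and find area = (L/4)^2 = 3
  sol <- ode_rk45(function(t, L) L * (1 - 2) + 2 * 4, 4, 0, 40,
                  rtol = 1e-10, atol = 1e-12,
                  events = function(t, L) (L / 4)^2 - 3)
  expect_equal(tr$lineage$time, sol$event$time, tolerance = 1e-5)

  ## threshold above the equilibrium area: no division ever
  m2 <- model_spec(species = list(X = list(init = 1)),
                   grow = grow_arrow(pressure = 1, growth_rate = 0,
                                     spring = 1),
                   divide = division_spec("errera", mean = 5, sd = 0))
  tr2 <- run_growing(m2, sq, 60, seed = 3, save_at = c(0, 60))
  expect_equal(n_cells(tr2$final$tissue), 1L)
})

test_that("identical seeds give identical lineages; state survives division", {
  sq <- unit_square_tissue()
  m <- model_spec(species = list(X = list(init = 1)),
                  grow = grow_arrow(pressure = 1, growth_rate = 0,
                                    spring = 1),
                  divide = division_spec("errera", mean = 2, sd = 0.2))
  tra <- run_growing(m, sq, 25, seed = 11, save_at = c(0, 25))
  trb <- run_growing(m, sq, 25, seed = 11, save_at = c(0, 25))
  expect_identical(tra$lineage, trb$lineage)
  expect_identical(tra$final$conc, trb$final$conc)

  ## amounts are conserved through division events (dilution-free species
  ## would halve in concentration only by area growth)
  g <- compute_geometry(tra$final$tissue)
  expect_equal(sum(tra$final$conc[, "X"] * g$area), 1, tolerance = 1e-3)
})

test_that("trajectories agree across integrator tolerances", {
  h <- hex_template(1)
  set.seed(21)
  m <- brusselator_model(D_A = 0.2, D_B = 0.6, perturb = 0.3)
  set.seed(21); tr1 <- run_static(m, h, 50, save_at = c(0, 50))
  set.seed(21); tr2 <- run_static(m, h, 50, save_at = c(0, 50),
                                  rtol = 1e-8, atol = 1e-11)
  expect_rel_equal(tr1$final$conc, tr2$final$conc, 1e-3)
})

test_that("snapshots export and round-trip through the mesh loaders", {
  sq <- unit_square_tissue()
  m <- model_spec(species = list(X = list(init = 2)),
                  grow = grow_arrow(pressure = 1, growth_rate = 0,
                                    spring = 1),
                  divide = division_spec("errera", mean = 2, sd = 0))
  tr <- run_growing(m, sq, 30, seed = 9, save_at = c(0, 30))
  dir <- withr::local_tempdir()
  snapshot(tr, dir = dir)
  ## t = 0 snapshot equals the input tissue
  t0 <- read_tissue(file.path(dir, "tissue_001.csv"), "flat")
  expect_equal(sort(compute_geometry(t0)$area),
               sort(compute_geometry(sq)$area), tolerance = 1e-9)
  cc <- utils::read.csv(file.path(dir, "conc_002.csv"))
  tN <- read_tissue(file.path(dir, "tissue_002.csv"), "flat")
  expect_equal(nrow(cc), n_cells(tN))
  ## every final cell id traces to a root initial cell
  roots <- clone_roots(tr$final$ids, tr$lineage)
  expect_true(all(roots == 1L))
  expect_true(file.exists(file.path(dir, "lineage.csv")))
})
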