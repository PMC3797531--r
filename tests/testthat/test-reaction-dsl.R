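test_that("arrow parsing produces canonical one-directional reactions", {
  r <- parse_arrow("A -> B", 2)
  expect_length(r, 1L)
  expect_equal(r[[1]]$reactants, c(A = 1L))
  expect_equal(r[[1]]$products, c(B = 1L))
  expect_s3_class(r[[1]]$rate, "mass_action")

  rev2 <- parse_arrow("A + 2B <-> C", list("k1", "k2"))
  expect_length(rev2, 2L)
  expect_equal(rev2[[1]]$reactants, c(A = 1L, B = 2L))
  expect_equal(rev2[[2]]$reactants, c(C = 1L))
  expect_equal(rev2[[2]]$products, c(A = 1L, B = 2L))

  src <- parse_arrow("0 -> A", 1.5)[[1]]
  expect_length(src$reactants, 0L)

  expect_error(parse_arrow("A = B", 1), "arrow")
  expect_error(parse_arrow("A <-> B", 1), "2 rate laws")
  expect_error(parse_arrow("1.5A -> B", 1), "parse")
})

test_that("mass-action terms follow the (f - e) k prod(X^e) rule", {
  rts <- mass_action_terms(parse_arrow("A -> B", 2))
  expect_equal(eval_terms(rts, c(A = 3, B = 0)), c(A = -6, B = 6))

  ## autocatalytic 2A + B -> 3A: net +1 for A, -1 for B, flux c A^2 B
  rts2 <- mass_action_terms(parse_arrow("2A + B -> 3A", mass_action("c")),
                            parameters = list(c = 0.7))
  st <- c(A = 1.3, B = 2.1)
  flux <- 0.7 * 1.3^2 * 2.1
  expect_equal(eval_terms(rts2, st), c(A = flux, B = -flux))

  ## zeroth-order source is state independent
  rts3 <- mass_action_terms(parse_arrow("0 -> A", 1.5))
  expect_equal(eval_terms(rts3, c(A = 100))[["A"]], 1.5)
  expect_equal(eval_terms(rts3, c(A = 0))[["A"]], 1.5)

  expect_error(mass_action_terms(parse_arrow("A -> B", -1)), "negative")
})

test_that("compiled mass-action RHS matches an independent hand-rule oracle", {
  ## oracle: direct triple loop over reactions/species applying
  ## dU_j/dt = (f_j - e_j) k prod_i X_i^{e_i}
  oracle_rhs <- function(reactions, x) {
    out <- setNames(numeric(length(x)), names(x))
    for (r in reactions) {
      flux <- r$k
      for (i in seq_along(r$e)) flux <- flux * x[[names(r$e)[i]]]^r$e[[i]]
      for (sp in union(names(r$e), names(r$f))) {
        e <- if (sp %in% names(r$e)) r$e[[sp]] else 0
        f <- if (sp %in% names(r$f)) r$f[[sp]] else 0
        out[sp] <- out[sp] + (f - e) * flux
      }
    }
    out
  }
  set.seed(101)
  species <- c("A", "B", "C", "D")
  for (rep in 1:100) {
    n_rx <- sample(1:5, 1)
    rxs <- list(); oracle <- list()
    for (j in seq_len(n_rx)) {
      ns <- sample(0:2, 1); np <- sample((if (ns == 0) 1 else 0):2, 1)
      lhs_sp <- sample(species, ns)
      rhs_sp <- sample(species, np)
      e <- setNames(sample(1:3, ns, replace = TRUE), lhs_sp)
      f <- setNames(sample(1:3, np, replace = TRUE), rhs_sp)
      k <- runif(1, 0.1, 2)
      side <- function(v) if (!length(v)) "0"
        else paste(v, names(v), collapse = " + ")
      rxs[[j]] <- parse_arrow(paste(side(e), "->", side(f)), k)[[1]]
      oracle[[j]] <- list(e = as.list(e), f = as.list(f), k = k)
    }
    x <- setNames(runif(4, 0, 2), species)
    got <- eval_terms(mass_action_terms(rxs), x)
    want <- oracle_rhs(oracle, x)
    expect_lt(max(abs(got[names(want)] - want)), 1e-10)
  }
})

test_that("regulatory rate laws reproduce their canonical half-max points", {
  ## Hill at half saturation
  rh <- reaction("X -> Y", hill(v = 1, n = 2, K = 0.5), enzyme = "E")
  expect_equal(eval_terms(regulatory_terms(rh),
                          c(X = 0.5, Y = 0, E = 1))[["Y"]], 0.5)
  ## GRN logistic(0) = 1/2; enzyme scales linearly
  rg <- reaction("X -> Y", grn(v = 2, T = 1, n = 1, h = 0), enzyme = "E")
  expect_equal(eval_terms(regulatory_terms(rg),
                          c(X = 0, Y = 0, E = 0.5))[["Y"]], 0.5)
  ## MM at K: v/2 produced, substrate consumed at the same rate
  rm <- reaction("X -> Y", mm(K = 2, v = 3), enzyme = "E")
  out <- eval_terms(regulatory_terms(rm), c(X = 2, Y = 0, E = 1))
  expect_equal(out[["Y"]], 1.5)
  expect_equal(out[["X"]], -1.5)
  ## NHCA with all weights zero: v E / (k + 1)
  rn <- reaction("X -> Y", nhca(v = 2, Tp = 0, Tm = 0, n = 1, m = 1,
                                k = 3), enzyme = "E")
  expect_equal(eval_terms(regulatory_terms(rn),
                          c(X = 5, Y = 0, E = 1))[["Y"]], 0.5)
  ## inputs are read, not consumed, for production laws
  expect_equal(eval_terms(regulatory_terms(rh),
                          c(X = 0.5, Y = 0, E = 1))[["X"]], 0)
  ## weight/input length mismatch is an error
  rbad <- reaction("X + Y -> Z", grn(v = 1, T = c(1, 2, 3), n = 1))
  expect_error(eval_terms(regulatory_terms(rbad), c(X = 1, Y = 1, Z = 0)),
               "length")
})

test_that("control functions are monotone, bounded in (0,1), with f(0)=1/2", {
  x <- seq(-20, 20, length.out = 401)
  for (f in list(ctrl_logistic, ctrl_sigma)) {
    y <- f(x)
    expect_true(all(diff(y) > 0))
    expect_true(all(y > 0 & y < 1))
    expect_equal(f(0), 0.5)
  }
  ## GRN term bounded by v*E
  rg <- reaction("X -> Y", grn(v = 3, T = 2, n = 1, h = 1,
                               control = "sigma"), enzyme = "E")
  ts <- regulatory_terms(rg)
  for (xv in c(0, 1, 100, 1e6))
    expect_lt(eval_terms(ts, c(X = xv, Y = 0, E = 2))[["Y"]], 6)
})

test_that("catalytic arrows expand to the elementary schemes", {
  rx4 <- expand_catalytic(catalytic_arrow("X", "Y", "E", c(1, 2, 3, 4)))
  expect_length(rx4, 4L)
  expect_setequal(species_of(rx4), c("X", "E", "X_E", "Y"))

  rx6 <- expand_catalytic(catalytic_arrow("X", "Y", "E", 1:6,
                                          intermediate = TRUE))
  expect_length(rx6, 6L)
  expect_setequal(species_of(rx6), c("X", "E", "X_E", "Y_E", "Y"))

  casc <- expand_catalytic(cascade_arrow(c("X", "Y", "Z"), "E", rep(1, 8)))
  expect_length(casc, 8L)
  expect_setequal(species_of(casc), c("X", "Y", "Z", "E", "X_E", "Y_E"))

  ## deterministic collision suffix
  rxc <- expand_catalytic(catalytic_arrow("X", "Y", "E", rep(1, 4)),
                          existing = "X_E")
  expect_true("X_E2" %in% species_of(rxc))

  expect_error(catalytic_arrow("X", "Y", "E", c(1, 2)), "4 rate constants")
})

test_that("catalytic expansion conserves total enzyme exactly", {
  set.seed(42)
  rx <- expand_catalytic(catalytic_arrow("X", "Y", "E", runif(4, 0.5, 2)))
  ts <- mass_action_terms(rx)
  for (i in 1:20) {
    x <- setNames(runif(4, 0, 3), c("X", "E", "X_E", "Y"))
    d <- eval_terms(ts, x)
    expect_equal(d[["E"]] + d[["X_E"]], 0)
  }
  rx6 <- expand_catalytic(catalytic_arrow("X", "Y", "E", runif(6, 0.5, 2),
                                          intermediate = TRUE))
  ts6 <- mass_action_terms(rx6)
  x <- setNames(runif(5, 0, 3), c("X", "E", "X_E", "Y_E", "Y"))
  d <- eval_terms(ts6, x)
  expect_equal(d[["E"]] + d[["X_E"]] + d[["Y_E"]], 0)
})

test_that("closed mass-action networks conserve total mass when integrated", {
  m <- model_spec(reactions = parse_arrow("A <-> B", list(1.3, 0.4)),
                  species = list(A = list(init = 2), B = list(init = 0.5)))
  tr <- run_static(m, unit_square_tissue(), 10)
  sums <- sapply(tr$snapshots, function(s) sum(s$conc))
  expect_lt(diff(range(sums)), 1e-6)
  ## equilibrium ratio k1/k2
  cf <- tr$final$conc
  expect_equal(unname(cf[1, "B"] / cf[1, "A"]), 1.3 / 0.4,
               tolerance = 1e-4)
})
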