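test_that("layer classification: L1 boundary, L2 subepidermal, TIP apex", {
  sq <- unit_square_tissue()
  ind <- classify_layers(sq)
  expect_equal(ind$L1, 1)
  expect_equal(ind$L2, 0)

  h <- hex_template(2)            # 19 cells: 12 boundary, 6 ring-1, 1 center
  ind2 <- classify_layers(h)
  expect_equal(sum(ind2$L1), 12)
  expect_equal(sum(ind2$L2), 6)
  expect_equal(sum(ind2$L1 == 0 & ind2$L2 == 0), 1)
  expect_equal(sum(ind2$L1 * ind2$L2), 0)      # disjoint

  ## pure function of topology: permuting cells permutes labels
  perm <- sample(n_cells(h))
  hp <- h; hp$C <- h$C[perm]
  indp <- classify_layers(hp)
  expect_equal(indp$L1, ind2$L1[perm])
  expect_equal(indp$L2, ind2$L2[perm])
})

test_that("pattern summary counts strict maxima and threshold domains", {
  h <- hex_template(2)
  g <- compute_geometry(h)
  uniform <- rep(1, 19)
  ps <- pattern_summary(uniform, h, high_threshold = 0.5, g = g)
  expect_equal(ps$n_maxima, 0)
  expect_equal(ps$n_domains, 1)

  peak <- rep(0, 19); peak[central_cells(h, 1, g)] <- 1
  ps1 <- pattern_summary(peak, h, high_threshold = 0.5, g = g)
  expect_equal(ps1$n_maxima, 1)
  expect_equal(ps1$n_domains, 1)

  ## two peaks separated by sub-threshold cells
  ctr <- g$centroid
  left <- which.min(ctr[, 1]); right <- which.max(ctr[, 1])
  two <- rep(0, 19); two[c(left, right)] <- 1
  ps2 <- pattern_summary(two, h, high_threshold = 0.5, g = g)
  expect_equal(ps2$n_maxima, 2)
  expect_equal(ps2$n_domains, 2)
})

test_that("well-mixed Brusselator sits at its analytic fixed point", {
  a <- 0.1; beta <- 0.1; b <- 0.15; cc <- 0.1
  ## b < 0.2: the well-mixed system is stable and settles at the fixed point
  m <- brusselator_model(a, beta, b, cc, D_A = 0, D_B = 0, perturb = 0)
  tr <- run_static(m, unit_square_tissue(), 2000, save_at = c(0, 2000))
  expect_equal(unname(tr$final$conc[1, "A"]), a / beta, tolerance = 1e-3)
  expect_equal(unname(tr$final$conc[1, "B"]), b * beta / (cc * a),
               tolerance = 1e-3)
})

test_that("equal diffusivities with uniform initial state never break symmetry", {
  h <- hex_template(1)
  m <- brusselator_model(D_A = 0.5, D_B = 0.5, perturb = 0,
                         open_boundary = FALSE)
  tr <- run_static(m, h, 300, save_at = c(0, 150, 300))
  for (sn in tr$snapshots) {
    expect_lt(diff(range(sn$conc[, "A"])), 1e-8)
    expect_lt(diff(range(sn$conc[, "B"])), 1e-8)
  }
})

test_that("ablation removes cells and keeps the mesh valid", {
  h <- hex_template(2)
  ha <- ablate_cells(h, central_cells(h, 3))
  expect_equal(n_cells(ha), 16L)
  expect_silent(validate_tissue(ha))
  expect_error(ablate_cells(h, 1:19), "every cell")
})

test_that("dome template is a mirror-symmetric half disk with a flat base", {
  d <- dome_template(3, side = 2)
  g <- compute_geometry(d)
  expect_true(all(g$centroid[, 2] > -0.5))
  ## mirror symmetry of the centroid multiset
  key <- function(x, y) {
    x <- round(x, 6); x[x == 0] <- 0
    y <- round(y, 6); y[y == 0] <- 0
    sort(sprintf("%.6f|%.6f", x, y))
  }
  expect_equal(key(-g$centroid[, 1], g$centroid[, 2]),
               key(g$centroid[, 1], g$centroid[, 2]))
})

test_that("organizer model without mechanical feedback grows uniformly", {
  d0 <- dome_template(2, side = 2)
  g0 <- compute_geometry(d0)
  m <- organizer_growth_model(p1 = 0, mu1 = 0, p0 = 0.005, spring = 0.01,
                              tip_frac = 0.2,
                              div_mean = 100 * mean(g0$area))
  sys <- compile_model(m, d0, static = FALSE)
  C <- init_conc(m, d0, sys$geom)
  C[, "W"] <- runif(n_cells(d0), 0, 5)       # W no longer matters
  Pv <- tessella:::cell_val(sys$mech$P, sys$geom, C)
  expect_equal(Pv, rep(0.005, n_cells(d0)))
  mur <- tessella:::edge_val(sys$mech$mu, sys$geom, C)
  expect_equal(mur, rep(5e-6, nrow(d0$E)))
})

test_that("SVG rendering is deterministic with rank-ordered colours", {
  t2 <- two_square_tissue()
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "a.svg"); f2 <- file.path(dir, "b.svg")
  render_tissue(t2, c(0.2, 0.9), f1)
  render_tissue(t2, c(0.2, 0.9), f2)
  expect_identical(readLines(f1), readLines(f2))
  svg <- readLines(f1)
  polys <- grep("<polygon", svg, value = TRUE)
  expect_length(polys, 2L)
  fills <- sub('.*fill="(#[0-9a-f]{6})".*', "\\1", polys)
  lum <- sapply(fills, function(h)
    sum(strtoi(substring(h, c(2, 4, 6), c(3, 5, 7)), 16L)))
  expect_gt(lum[1], lum[2])    # higher value = darker fill

  sq <- unit_square_tissue()
  f3 <- file.path(dir, "c.svg")
  render_tissue(sq, 1, f3)
  expect_length(grep("<polygon", readLines(f3)), 1L)
})
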