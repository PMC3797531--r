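test_that("FLAT rows load into validated meshes with shared walls", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("0,0, 1,0, 1,1, 0,1", f)
  t1 <- read_tissue(f, "flat")
  expect_equal(n_cells(t1), 1L)
  expect_equal(nrow(t1$V), 4L)
  expect_equal(nrow(t1$E), 4L)

  writeLines(c("0,0, 1,0, 1,1, 0,1", "1,0, 2,0, 2,1, 1,1"), f)
  t2 <- read_tissue(f, "flat")
  expect_equal(n_cells(t2), 2L)
  expect_equal(nrow(t2$V), 6L)
  expect_equal(nrow(t2$E), 7L)
  g <- compute_geometry(t2)
  shared <- which(!g$boundary_edge)
  expect_length(shared, 1L)
  expect_setequal(g$edge_cells[shared, ], 1:2)
})

test_that("both CSV dialects round-trip topology and coordinates", {
  t0 <- hex_template(2)
  g0 <- compute_geometry(t0)
  dir <- withr::local_tempdir()

  fl <- file.path(dir, "t.csv")
  write_tissue(t0, fl, "flat")
  t1 <- read_tissue(fl, "flat")
  expect_equal(n_cells(t1), n_cells(t0))
  expect_equal(nrow(t1$E), nrow(t0$E))
  expect_equal(sort(compute_geometry(t1)$area), sort(g0$area),
               tolerance = 1e-12)

  pre <- file.path(dir, "t")
  write_tissue(t0, pre, "vec")
  t2 <- read_tissue(pre, "vec")
  expect_equal(t2$V, t0$V)
  expect_equal(nrow(t2$E), nrow(t0$E))

  ## VEC -> FLAT -> VEC preserves areas to 1e-12
  write_tissue(t2, fl, "flat")
  t3 <- read_tissue(fl, "flat")
  expect_lt(max(abs(sort(compute_geometry(t3)$area) - sort(g0$area))),
            1e-12)

  ## bit-stable output
  fl2 <- file.path(dir, "t2.csv")
  write_tissue(t0, fl2, "flat")
  expect_identical(readLines(fl), readLines(fl2))

  ## empty tissue: header-only files
  te <- tissue(matrix(0, 0, 2), matrix(0L, 0, 2), list(), validate = FALSE)
  pre_e <- file.path(dir, "empty")
  write_tissue(te, pre_e, "vec")
  expect_equal(readLines(paste0(pre_e, "_vertices.csv")), "id,x,y")
  expect_equal(readLines(paste0(pre_e, "_edges.csv")), "id,v1,v2")
})

test_that("geometry cache: areas, centroids, lengths, outward normals", {
  sq <- unit_square_tissue()
  g <- compute_geometry(sq)
  expect_equal(g$area, 1)
  expect_equal(g$centroid[1, ], c(0.5, 0.5))

  t35 <- tissue(rbind(c(0, 0), c(3, 4), c(0, 4)),
                rbind(c(1, 2), c(2, 3), c(3, 1)), list(1:3))
  expect_equal(compute_geometry(t35)$edge_len[1], 5)

  ## bottom edge of the unit square has outward normal (0, -1)
  bot <- which(g$loop_edge == 1L)   # edge 1 connects (0,0)-(1,0)
  expect_equal(g$normals[bot, ], c(0, -1))
  ## all normals are unit and point away from the centroid
  for (i in seq_along(g$loop_edge)) {
    expect_equal(sqrt(sum(g$normals[i, ]^2)), 1)
    mid <- (sq$V[g$loop_v[i], ] + sq$V[g$loop_nx[i], ]) / 2
    expect_gt(sum(g$normals[i, ] * (mid - g$centroid[1, ])), 0)
  }
})

test_that("polygon closure: sum of length-weighted outward normals is zero", {
  set.seed(3)
  for (i in 1:10) {
    P <- random_convex_polygon(n = sample(5:10, 1))
    t1 <- tissue_from_polygons(list(P))
    g <- compute_geometry(t1)
    s <- colSums(g$edge_len[g$loop_edge] * g$normals)
    expect_lt(max(abs(s)), 1e-10)
  }
})

test_that("invalid meshes are rejected with the offending cells named", {
  V <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  ## dangling edge index
  expect_error(tissue(V, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1)),
                      list(c(1:4, 9L))),
               "cell 1")
  ## open chain (edges that do not close)
  expect_error(tissue(V, rbind(c(1, 2), c(2, 3), c(3, 4)), list(1:3)),
               "close|chain")
  ## self-intersecting bow-tie
  Vb <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  Eb <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1))
  expect_error(tissue(Vb, Eb, list(1:4)), "self-intersect|area")
  ## edge in three cells
  expect_error(
    tissue_from_polygons(list(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
                              rbind(c(1, 0), c(2, 0), c(2, 1), c(1, 1)),
                              rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))),
    "more than two cells|repeated")
})

test_that("winding is normalised counter-clockwise on load", {
  ## clockwise input polygon
  t1 <- tissue_from_polygons(list(rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0))))
  loop <- tessella:::cell_loop_vertices(t1, 1)
  expect_gt(tessella:::signed_area(t1$V[loop, ]), 0)
})

test_that("FLAT reconstruction of any tissue recovers the edge multiset", {
  t0 <- random_tissue(10, seed = 9)
  f <- withr::local_tempfile(fileext = ".csv")
  write_tissue(t0, f, "flat")
  t1 <- read_tissue(f, "flat")
  edge_key <- function(t) {
    a <- t$V[t$E[, 1], , drop = FALSE]; b <- t$V[t$E[, 2], , drop = FALSE]
    lo <- pmin(a[, 1], b[, 1]); hi <- pmax(a[, 1], b[, 1])
    lo2 <- pmin(a[, 2], b[, 2]); hi2 <- pmax(a[, 2], b[, 2])
    sort(sprintf("%.8f|%.8f|%.8f|%.8f", lo, lo2, hi, hi2))
  }
  expect_equal(edge_key(t1), edge_key(t0))
})
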