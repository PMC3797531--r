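## Shared fixtures, all built in code.

unit_square_tissue <- function(s = 1) {
  tissue(rbind(c(0, 0), c(s, 0), c(s, s), c(0, s)),
         rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1)),
         list(1:4))
}

## two unit squares sharing a vertical side
two_square_tissue <- function() {
  tissue_from_polygons(list(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
                            rbind(c(1, 0), c(2, 0), c(2, 1), c(1, 1))))
}

## random convex polygon: convex hull of n random points
random_convex_polygon <- function(n = 8, scale = 1) {
  repeat {
    P <- matrix(stats::runif(2 * n, -scale, scale), ncol = 2)
    h <- grDevices::chull(P)
    if (length(h) >= 4) break
  }
  P <- P[rev(h), , drop = FALSE]          # chull is clockwise; reverse
  if (tessella:::signed_area(P) < 0) P <- P[rev(seq_len(nrow(P))), ]
  P
}

## brute-force Errera oracle: scan both endpoints along the perimeter at
## the given resolution, solving the equal-area constraint exactly
errera_oracle_scan <- function(P, res = 1e-3) {
  bp <- tessella:::boundary_param(P)
  n <- max(ceiling(1 / res), 100L)
  s_grid <- seq(0, bp$L, length.out = n + 1L)[-(n + 1L)]
  best <- Inf
  for (s1 in s_grid) {
    s2 <- tessella:::equal_area_partner(bp, s1)
    p1 <- tessella:::param_point(bp, s1)$pt
    p2 <- tessella:::param_point(bp, s2)$pt
    d <- sqrt(sum((p2 - p1)^2))
    if (d < best) best <- d
  }
  best
}

## small random Voronoi tissue for surgery/conservation tests
random_tissue <- function(n_cells = 12, seed = NULL) {
  voronoi_template("circle", n_cells, seed = seed, radius = 3)
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y)) / max(abs(y), 1e-300), tol)
}
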