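test_that("uniform unit resistance reproduces hand-computed costs on a
           3x3 grid", {
  res <- make_uniform_resistance(3)
  src <- data.frame(x = 1.5, y = 1.5)  # the center cell
  d <- cost_distance(res, src)
  m <- matrix(d[1, ], 3, 3)
  expect_equal(m[2, 2], 0)
  expect_equal(m[1, 2], 1)
  expect_equal(m[2, 1], 1)
  expect_equal(m[1, 1], sqrt(2), tolerance = 1e-12)
})

test_that("Dijkstra cost distance matches Bellman-Ford on random
           fixtures, every cell", {
  for (seed in 1:3) {
    set.seed(seed)
    v <- matrix(runif(15 * 15, 0.5, 20), 15, 15)
    if (seed == 3) v[sample(225, 10)] <- NA  # nodata holes
    res <- raster_grid(v, cell_size = 1)
    src_cell <- which(!is.na(v))[1]
    r0 <- (src_cell - 1) %% 15 + 1; c0 <- (src_cell - 1) %/% 15 + 1
    p <- cell_center(res, r0, c0)
    d <- cost_distance(res, data.frame(x = p$x, y = p$y))
    bf <- bf_cost_distance(v, 1, src_cell)
    bf[is.na(as.vector(v))] <- Inf
    expect_equal(as.vector(d[1, ]), bf, tolerance = 1e-9)
  }
})

test_that("sources on nodata or outside the extent are rejected by
           name", {
  v <- matrix(1, 4, 4); v[2, 2] <- NA
  res <- raster_grid(v, cell_size = 1)
  p <- cell_center(res, 2, 2)
  expect_error(cost_distance(res, data.frame(x = p$x, y = p$y)), "nodata")
  expect_error(cost_distance(res, data.frame(x = 99, y = 1)), "extent")
})

test_that("resistant kernels decay linearly with cost and superpose", {
  res <- make_uniform_resistance(3)
  src <- data.frame(x = 1.5, y = 1.5)
  k <- resistant_kernel(res, src, threshold = 2)
  expect_equal(k$values[2, 2], 1)
  expect_equal(k$values[1, 2], 0.5)
  expect_equal(k$values[1, 1], 1 - sqrt(2) / 2, tolerance = 1e-12)
  # two coincident sources double the surface exactly
  k2 <- resistant_kernel(res, rbind(src, src), threshold = 2)
  expect_equal(k2$values, 2 * k$values, tolerance = 1e-12)
  expect_error(resistant_kernel(res, src[0, ], threshold = 2), "source")
})

test_that("kernel support grows monotonically with the dispersal
           threshold", {
  set.seed(4)
  res <- raster_grid(matrix(runif(400, 1, 30), 20, 20), cell_size = 1)
  src <- data.frame(x = 10.5, y = 10.5)
  kA <- resistant_kernel(res, src, threshold = 10)
  kB <- resistant_kernel(res, src, threshold = 25)
  expect_true(all((kA$values > 0) <= (kB$values > 0)))
  expect_true(all(kB$values >= kA$values - 1e-12))
})

test_that("an isolated source cell scores exactly 1", {
  v <- matrix(NA_real_, 5, 5); v[3, 3] <- 1
  res <- raster_grid(v, cell_size = 1)
  p <- cell_center(res, 3, 3)
  k <- resistant_kernel(res, data.frame(x = p$x, y = p$y), threshold = 5)
  expect_equal(k$values[3, 3], 1)
  expect_true(all(is.na(k$values[-13])))
})

test_that("least-cost paths take the straight route on uniform strips
           and detour through gaps in walls", {
  res <- make_uniform_resistance(5)
  a <- cell_center(res, 3, 1); b <- cell_center(res, 3, 5)
  lp <- least_cost_path(res, a, b)
  expect_equal(lp$cost, 4)
  expect_equal(length(lp$cells), 5)
  expect_true(all(lp$coords$y == a$y))  # straight row

  # identical endpoints: single-cell path, zero cost
  same <- least_cost_path(res, a, a)
  expect_equal(same$cost, 0)
  expect_length(same$cells, 1)

  # wall with a gap: the path must pass the gap cell
  v <- matrix(1, 7, 7); v[, 4] <- 1000; v[6, 4] <- 1
  wres <- raster_grid(v, cell_size = 1)
  a2 <- cell_center(wres, 2, 1); b2 <- cell_center(wres, 2, 7)
  lp2 <- least_cost_path(wres, a2, b2)
  gap_cell <- (4 - 1) * 7 + 6  # column-major index of the gap
  expect_true(gap_cell %in% lp2$cells)
  # cost agrees with the brute-force oracle
  src_cell <- (1 - 1) * 7 + 2
  bf <- bf_cost_distance(v, 1, src_cell)
  dst_cell <- (7 - 1) * 7 + 2
  expect_equal(lp2$cost, bf[dst_cell], tolerance = 1e-9)
})

test_that("cost distances are symmetric", {
  set.seed(6)
  res <- raster_grid(matrix(runif(144, 1, 50), 12, 12), cell_size = 1)
  a <- cell_center(res, 2, 3); b <- cell_center(res, 11, 9)
  dab <- least_cost_path(res, a, b)$cost
  dba <- least_cost_path(res, b, a)$cost
  expect_equal(dab, dba, tolerance = 1e-9)
})

test_that("factorial least-cost-path density counts all reachable
           pairs and respects the bandwidth limit", {
  res <- make_uniform_resistance(15)
  pts <- data.frame(x = c(3.5, 11.5, 7.5), y = c(7.5, 7.5, 11.5))
  dens <- factorial_lcp_density(res, pts, max_cost = 100, bandwidth = 0)
  expect_equal(attr(dens, "n_paths"), 3)  # n(n-1)/2 pairs
  expect_equal(attr(dens, "n_pairs"), 3)

  # bandwidth 0: support is exactly the union of raw path cells
  cg <- cost_graph(res)
  cells <- unique(unlist(lapply(list(c(1, 2), c(1, 3), c(2, 3)), function(p)
    least_cost_path(cg, pts[p[1], ], pts[p[2], ])$cells)))
  expect_setequal(which(dens$values > 0), cells)

  # Gaussian buffering preserves each path's mass away from edges
  dens2 <- factorial_lcp_density(res, pts, max_cost = 100, bandwidth = 1)
  expect_equal(sum(dens2$values), sum(dens$values), tolerance = 0.02)

  # two sources on a uniform strip: ridge along the straight segment,
  # symmetric about it
  strip <- make_uniform_resistance(11)
  p2 <- data.frame(x = c(1.5, 9.5), y = c(5.5, 5.5))
  d2 <- factorial_lcp_density(strip, p2, max_cost = 100, bandwidth = 1.5)
  ridge_row <- 6
  expect_true(all(d2$values[ridge_row, 3:9] >=
                    d2$values[ridge_row - 2, 3:9]))
  expect_equal(d2$values[ridge_row - 1, 3:9], d2$values[ridge_row + 1, 3:9],
               tolerance = 1e-9)

  # unreachable pairs give a zero surface with a warning
  expect_warning(
    z <- factorial_lcp_density(strip, p2, max_cost = 0.5, bandwidth = 1),
    "reachable")
  expect_true(all(z$values == 0))
  expect_error(factorial_lcp_density(strip, p2[1, , drop = FALSE]),
               "two source")
})

test_that("uniform resistance yields an isotropic kernel with support
           radius equal to the threshold within one cell", {
  res <- raster_grid(matrix(1, 41, 41), cell_size = 250)
  ctr <- cell_center(res, 21, 21)
  thr <- 2000
  k <- resistant_kernel(res, data.frame(x = ctr$x, y = ctr$y), thr)
  cc <- grid_cell_centers(res)
  dist <- sqrt((cc$x - ctr$x)^2 + (cc$y - ctr$y)^2)
  pos <- as.vector(k$values) > 0
  expect_lte(max(dist[pos]), thr + 250)          # support within threshold
  expect_true(all(pos[dist <= thr - 250]))       # disc interior covered
})
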