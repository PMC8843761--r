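test_that("terrain derivatives are exact on flat and inclined planes", {
  flat <- raster_grid(matrix(1000, 10, 10), cell_size = 250)
  td <- terrain_derivatives(flat)
  expect_true(all(td$slope$values == 0))
  expect_true(all(td$tri$values == 0))
  expect_true(all(abs(td$slope_position$values) < 1e-9))

  # plane rising 1 m per cell toward the east
  cs <- 30
  z <- matrix(rep(1:12, each = 8), 8, 12)
  incl <- raster_grid(z, cell_size = cs)
  td2 <- terrain_derivatives(incl)
  inner <- td2$slope$values[2:7, 2:11]
  expect_equal(inner, matrix(atan(1 / cs) * 180 / pi, 6, 10),
               tolerance = 1e-9)
  expect_error(terrain_derivatives(raster_grid(matrix(0, 2, 2))), "3x3")
})

test_that("TRASP maps the 30- and 210-degree azimuths to its endpoints", {
  cs <- 100
  mk_plane <- function(az_deg) {
    # elevation decreasing toward azimuth az (downslope direction az)
    az <- az_deg * pi / 180
    g <- raster_grid(matrix(0, 9, 9), cell_size = cs)
    cc <- grid_cell_centers(g)
    g$values <- matrix(-(sin(az) * cc$x + cos(az) * cc$y) * 0.1, 9, 9)
    g
  }
  t30 <- terrain_derivatives(mk_plane(30))
  expect_equal(max(abs(t30$trasp$values[3:7, 3:7])), 0, tolerance = 1e-9)
  t210 <- terrain_derivatives(mk_plane(210))
  expect_equal(min(t210$trasp$values[3:7, 3:7]), 1, tolerance = 1e-9)
})

test_that("focal mean matches the brute-force reference everywhere", {
  set.seed(2)
  m <- matrix(rnorm(400), 20, 20)
  m[c(5, 107, 300)] <- NA
  g <- raster_grid(m, cell_size = 250)
  for (radius in c(300, 750, 1500)) {
    fast <- focal_mean(g, radius)$values
    slow <- bf_focal_mean(m, radius / 250)
    expect_equal(fast, slow, tolerance = 1e-9)
  }
})

test_that("focal mean handles degenerate and analytic cases", {
  const <- raster_grid(matrix(7, 10, 10), cell_size = 250)
  expect_true(all(focal_mean(const, 1000)$values == 7))

  # unit impulse: every covered interior cell averages 1/k
  z <- matrix(0, 15, 15); z[8, 8] <- 1
  g <- raster_grid(z, cell_size = 250)
  fm <- focal_mean(g, 500)  # 2-cell radius window, k = 13 cells
  k <- sum(outer((-2):2, (-2):2, function(a, b) a^2 + b^2) <= 4)
  expect_equal(fm$values[8, 8], 1 / k, tolerance = 1e-12)
  expect_equal(fm$values[8, 10], 1 / k, tolerance = 1e-12)
  expect_equal(fm$values[8, 11], 0)

  expect_warning(out <- focal_mean(g, 100), "half a cell")
  expect_identical(out$values, g$values)
})

test_that("window metrics reproduce hand-computed values on the 7x7
           two-block fixture", {
  lc <- two_block_landcover()  # class 4: 21 cells, class 5: 28 cells
  r <- 2200  # window covers the whole 7x7 grid from every cell
  # hand-derived: N = 49, area = 306.25 ha, one patch per class,
  # 7 boundary edges of 250 m
  expect_equal(window_metric(lc, "PLAND", r, "class", 4)$values[4, 4],
               100 * 21 / 49)
  expect_equal(window_metric(lc, "LPI", r, "class", 4)$values[4, 4],
               100 * 21 / 49)
  expect_equal(window_metric(lc, "LPI", r)$values[4, 4], 100 * 28 / 49)
  expect_equal(window_metric(lc, "PD", r)$values[4, 4],
               2 / 306.25 * 100)
  expect_equal(window_metric(lc, "ED", r)$values[4, 4],
               7 * 250 / 306.25)
  expect_equal(window_metric(lc, "SHDI", r)$values[4, 4],
               -(21 / 49 * log(21 / 49) + 28 / 49 * log(28 / 49)))
  # both blocks are maximally aggregated rectangles: AI = 100
  expect_equal(window_metric(lc, "AI", r)$values[4, 4], 100)
  # every cell sees the same full-grid window
  expect_true(all(window_metric(lc, "SHDI", r)$values ==
                    window_metric(lc, "SHDI", r)$values[1, 1]))
})

test_that("AI and PD respond to fragmentation as hand-computed", {
  # 7x7 of class 4 with a single class-5 cell at the center:
  # g_44 = 84 - 4 = 80 like adjacencies, max for 48 cells = 82
  m <- matrix(4, 7, 7); m[4, 4] <- 5
  lc <- raster_grid(m, cell_size = 250)
  expect_equal(window_metric(lc, "AI", 2200)$values[1, 1],
               (48 / 49) * (80 / 82) * 100, tolerance = 1e-12)
  expect_equal(window_metric(lc, "PD", 2200)$values[1, 1],
               2 / 306.25 * 100)
  expect_equal(window_metric(lc, "ED", 2200)$values[1, 1],
               4 * 250 / 306.25)
  # checkerboard has no like adjacencies: AI = 0
  cb <- raster_grid(outer(1:4, 1:4, "+") %% 2 + 1, cell_size = 250)
  expect_equal(window_metric(cb, "AI", 2000)$values[2, 2], 0)
})

test_that("single-class windows give the degenerate metric values", {
  lc <- raster_grid(matrix(4, 7, 7), cell_size = 250)
  expect_equal(window_metric(lc, "PLAND", 2200, "class", 4)$values[4, 4], 100)
  expect_equal(window_metric(lc, "SHDI", 2200)$values[4, 4], 0)
  expect_equal(window_metric(lc, "ED", 2200)$values[4, 4], 0)
  expect_equal(window_metric(lc, "PD", 2200)$values[4, 4],
               1 / 306.25 * 100)  # one patch per window area
  # two classes at equal proportion: SHDI = ln 2
  half <- raster_grid(matrix(c(rep(1, 24), rep(2, 24)), 6, 8),
                      cell_size = 250)
  expect_equal(window_metric(half, "SHDI", 3000)$values[3, 4], log(2))
})

test_that("metrics are invariant or covariant under class relabeling as
           mathematically required", {
  set.seed(3)
  m <- matrix(sample(c(4, 5), 100, replace = TRUE), 10, 10)
  lc <- raster_grid(m, cell_size = 250)
  swapped <- raster_grid(ifelse(m == 4, 5, 4), cell_size = 250)
  for (met in c("SHDI", "PD", "ED", "AI"))
    expect_equal(window_metric(lc, met, 1000)$values,
                 window_metric(swapped, met, 1000)$values,
                 info = met)
  expect_equal(window_metric(lc, "PLAND", 1000, "class", 4)$values,
               window_metric(swapped, "PLAND", 1000, "class", 5)$values)
})

test_that("PLAND converges to the landscape proportion as the window
           grows", {
  set.seed(4)
  m <- matrix(sample(c(4, 5), 225, replace = TRUE, prob = c(0.3, 0.7)),
              15, 15)
  lc <- raster_grid(m, cell_size = 250)
  target <- 100 * mean(m == 4)
  err <- vapply(c(500, 1500, 6000), function(r)
    abs(window_metric(lc, "PLAND", r, "class", 4)$values[8, 8] - target), 0)
  expect_lt(err[3], 1e-9)  # full-grid window equals the global proportion
  expect_lte(err[3], err[1])
})

test_that("window metrics validate class codes and levels", {
  lc <- raster_grid(matrix(c(4, 5, 9, 4), 2, 2), cell_size = 250)
  expect_error(window_metric(lc, "SHDI", 500), "unknown")
  ok <- two_block_landcover()
  expect_error(window_metric(ok, "PLAND", 500), "class-level")
  expect_error(window_metric(ok, "SHDI", 500, "class", 4), "landscape-level")
})

test_that("distance surfaces match analytic and brute-force references", {
  g <- raster_grid(matrix(0, 12, 12), cell_size = 250)
  # a cell containing a feature point is within half a cell diagonal
  pt <- data.frame(x = 1100, y = 1600)
  d1 <- distance_to_features(pt, g)
  expect_lte(d1$values[grid_rowcol(g, pt$x, pt$y)$row,
                       grid_rowcol(g, pt$x, pt$y)$col],
             250 * sqrt(2) / 2)
  # single point: closed-form Euclidean distance field
  cc <- grid_cell_centers(g)
  expect_equal(as.vector(d1$values),
               sqrt((cc$x - 1100)^2 + (cc$y - 1600)^2), tolerance = 1e-9)
  # several points: brute-force nearest-point scan
  set.seed(5)
  pts <- data.frame(x = runif(7, 0, 3000), y = runif(7, 0, 3000))
  dm <- distance_to_features(pts, g)
  bf <- apply(cbind(cc$x, cc$y), 1, function(p)
    min(sqrt((pts$x - p[1])^2 + (pts$y - p[2])^2)))
  expect_equal(as.vector(dm$values), bf, tolerance = 1e-9)
  expect_error(distance_to_features(data.frame(x = numeric(0),
                                               y = numeric(0)), g),
               "empty")
  # polyline: distance to a vertical line x = 1500
  ln <- cbind(x = c(1500, 1500), y = c(-1e5, 1e5))
  dl <- distance_to_features(ln, g)
  expect_equal(as.vector(dl$values), abs(cc$x - 1500), tolerance = 1e-9)
})

test_that("feature densities follow the analytic window formulas", {
  g <- raster_grid(matrix(0, 20, 20), cell_size = 250)
  none <- feature_density(data.frame(x = numeric(0), y = numeric(0)),
                          1000, g)
  expect_true(all(none$values == 0))

  # one point at a cell center: density 1/(pi r^2) at that cell
  ctr <- cell_center(g, 10, 10)
  one <- feature_density(data.frame(x = ctr$x, y = ctr$y), 1000, g)
  expect_equal(one$values[10, 10], 1 / (pi * 1^2), tolerance = 1e-12)

  # straight road through the window: length = chord = 2r (5% tolerance)
  road <- cbind(x = c(-1e4, 6e4), y = c(ctr$y, ctr$y))
  r_km <- 1.1
  dens <- feature_density(road, r_km * 1000, g)
  chord_km <- 2 * r_km  # the road passes through the window center
  expect_equal(dens$values[10, 10], chord_km / (pi * r_km^2),
               tolerance = 0.05)
})

test_that("the multiscale stack contains the full Table-style vocabulary:
           16 scalable variables x scales + 3 distance layers", {
  ls1 <- synthetic_landscape(landscape_config(seed = 8, nrow = 45,
                                              ncol = 45))
  base <- list(elevation = ls1$terrain, npp = ls1$npp, bamboo = ls1$bamboo,
               landcover = ls1$landcover,
               villages = ls1$features$villages,
               roads_major = ls1$features$roads[
                 ls1$features$road_class == "major"],
               roads_minor = ls1$features$roads[
                 ls1$features$road_class == "minor"])
  stack <- build_multiscale_stack(base, scales = c(1000, 2000))
  expect_length(stack$layers, 16 * 2 + 3)
  expect_true(all(c("BAM_1000", "Densvil_2000", "Disvil") %in%
                    names(stack$layers)))

  single <- build_multiscale_stack(base, scales = 1000)
  expect_length(single$layers, 16 + 3)

  # layer naming round-trips through file write / read
  dir <- tempfile()
  write_stack(single, dir)
  back <- read_stack(dir)
  expect_setequal(names(back$layers), names(single$layers))
  expect_equal(back$layers[["BAM_1000"]]$values,
               single$layers[["BAM_1000"]]$values, tolerance = 1e-12)
  unlink(dir, recursive = TRUE)

  # misaligned base layers are rejected
  base_bad <- base
  base_bad$npp <- raster_grid(matrix(0, 10, 10), cell_size = 250)
  expect_error(build_multiscale_stack(base_bad, scales = 1000),
               "aligned")
})
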