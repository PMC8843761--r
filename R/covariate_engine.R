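# Land-cover class codes used throughout: 1 crop, 2 shrub, 3 grass,
# 4 closed broadleaf forest (CBF), 5 closed needleleaf forest (CNF),
# 6 open forest (OF), 7 non-vegetation.
LC_CBF <- 4L
LC_CNF <- 5L

#' Terrain derivatives from a DEM
#'
#' Computes, on square cells with edge replication at the raster border:
#' * `slope`: degrees, 3x3 Horn gradient;
#' * `trasp`: aspect transformed to \[0, 1\] as
#'   `(1 - cos(pi/180 * (aspect - 30))) / 2`, so cool NNE slopes score 0 and
#'   warm SSW slopes 1 (flat cells are set to the neutral 0.5);
#' * `tri`: terrain ruggedness index, mean absolute elevation difference to
#'   the 8 neighbors;
#' * `slope_position`: elevation minus the focal mean elevation within
#'   `tpi_radius` (a topographic position index).
#'
#' @param dem elevation [raster_grid()] in meters.
#' @param tpi_radius neighborhood radius (m) for slope position.
#' @return list of [raster_grid()]s: `slope`, `trasp`, `tri`,
#'   `slope_position`.
#' @export
terrain_derivatives <- function(dem, tpi_radius = 750) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3 || nc < 3) stop("dem must be at least 3x3")
  cs <- dem$cell_size
  pad <- z[c(1, 1:nr, nr), c(1, 1:nc, nc)]
  sub <- function(dr, dc) pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  zNW <- sub(-1, -1); zN <- sub(-1, 0); zNE <- sub(-1, 1)
  zW  <- sub(0, -1);                    zE  <- sub(0, 1)
  zSW <- sub(1, -1);  zS <- sub(1, 0);  zSE <- sub(1, 1)
  gx <- ((zNE + 2 * zE + zSE) - (zNW + 2 * zW + zSW)) / (8 * cs)  # +east
  gy <- ((zNW + 2 * zN + zNE) - (zSW + 2 * zS + zSE)) / (8 * cs)  # +north
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  aspect <- (atan2(-gx, -gy) * 180 / pi) %% 360  # downslope azimuth
  trasp <- (1 - cos(pi / 180 * (aspect - 30))) / 2
  trasp[gx == 0 & gy == 0] <- 0.5
  tri <- (abs(z - zNW) + abs(z - zN) + abs(z - zNE) + abs(z - zW) +
            abs(z - zE) + abs(z - zSW) + abs(z - zS) + abs(z - zSE)) / 8
  mk <- function(m) raster_grid(m, xmin = dem$xmin, ymin = dem$ymin,
                                cell_size = cs, crs = dem$crs)
  tpi <- z - focal_mean(dem, tpi_radius)$values
  list(slope = mk(slope), trasp = mk(trasp), tri = mk(tri),
       slope_position = mk(tpi))
}

#' Focal mean over a circular window
#'
#' Each output cell is the mean of input values whose cell centers lie
#' within `radius` of the focal cell center; the window is truncated at the
#' raster edge and nodata cells are excluded from both numerator and
#' denominator.
#'
#' @param raster a [raster_grid()].
#' @param radius window radius in meters.
#' @return a [raster_grid()].
#' @export
focal_mean <- function(raster, radius) {
  if (radius < raster$cell_size / 2) {
    warning("radius smaller than half a cell; returning the input unchanged")
    return(raster)
  }
  out <- cpp_focal_stat(raster$values, radius / raster$cell_size, 0L)
  raster_grid(out, xmin = raster$xmin, ymin = raster$ymin,
              cell_size = raster$cell_size, crs = raster$crs)
}

focal_sum <- function(raster, radius) {
  out <- cpp_focal_stat(raster$values, radius / raster$cell_size, 1L)
  raster_grid(out, xmin = raster$xmin, ymin = raster$ymin,
              cell_size = raster$cell_size, crs = raster$crs)
}

#' Moving-window landscape metrics
#'
#' FRAGSTATS-style composition and configuration metrics computed for every
#' cell over a circular window (cell centers within `radius`), truncated at
#' the raster edge, over valid cells only. Patches are 8-connected and
#' clipped to the window.
#'
#' Metrics: `PLAND` (percent of window in the focal class), `LPI` (largest
#' patch as percent of window; largest patch of any class at landscape
#' level), `PD` (patches per 100 ha), `ED` (meters of class boundary per
#' ha, single-count cell edges), `SHDI` (Shannon diversity of class
#' proportions), `AI` (landscape aggregation index: proportion-weighted
#' like-adjacency ratio x 100, single-count rook adjacencies).
#'
#' @param landcover categorical [raster_grid()] with integer class codes.
#' @param metric one of `"PLAND"`, `"LPI"`, `"PD"`, `"ED"`, `"SHDI"`,
#'   `"AI"`.
#' @param radius window radius (m).
#' @param level `"landscape"` or `"class"`; a focal `class` is required
#'   iff `level == "class"` and only `PLAND`/`LPI` support it.
#' @param class focal class code (class level only).
#' @param classes allowed class codes; other codes raise an error.
#' @return a [raster_grid()].
#' @export
window_metric <- function(landcover, metric, radius,
                          level = c("landscape", "class"), class = NULL,
                          classes = 1:7) {
  level <- match.arg(level)
  metric <- match.arg(metric, c("PLAND", "LPI", "PD", "ED", "SHDI", "AI"))
  v <- landcover$values
  seen <- unique(v[!is.na(v)])
  if (any(!seen %in% classes))
    stop(sprintf("unknown land-cover class code(s): %s",
                 paste(setdiff(seen, classes), collapse = ", ")))
  if (level == "class") {
    if (is.null(class)) stop("class-level metrics need a focal class")
    if (!metric %in% c("PLAND", "LPI"))
      stop(sprintf("%s is a landscape-level metric", metric))
  } else if (metric == "PLAND") {
    stop("PLAND is a class-level metric; give level = 'class' and a class")
  } else {
    class <- -1L
  }
  code <- match(metric, c("PLAND", "LPI", "PD", "ED", "SHDI", "AI"))
  im <- v; storage.mode(im) <- "integer"
  out <- cpp_window_metric(im, radius / landcover$cell_size, code,
                           as.integer(class %||% -1L), landcover$cell_size)
  raster_grid(out, xmin = landcover$xmin, ymin = landcover$ymin,
              cell_size = landcover$cell_size, crs = landcover$crs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# point-to-segment distances, vectorized over points
seg_dist <- function(px, py, x1, y1, x2, y2) {
  vx <- x2 - x1; vy <- y2 - y1
  L2 <- vx^2 + vy^2
  if (L2 == 0) return(sqrt((px - x1)^2 + (py - y1)^2))
  t <- pmin(pmax(((px - x1) * vx + (py - y1) * vy) / L2, 0), 1)
  sqrt((px - (x1 + t * vx))^2 + (py - (y1 + t * vy))^2)
}

#' Euclidean distance to the nearest feature
#'
#' Per-cell distance (m) from the cell center to the nearest point (for a
#' data.frame of points) or to the nearest polyline segment (for a list of
#' coordinate matrices).
#'
#' @param features data.frame with `x`, `y`, or a list of two-column
#'   coordinate matrices (polylines), or a single matrix.
#' @param template [raster_grid()] defining the output geometry.
#' @return a [raster_grid()] of distances in meters.
#' @export
distance_to_features <- function(features, template) {
  cc <- grid_cell_centers(template)
  d <- rep(Inf, nrow(cc))
  if (is.data.frame(features)) {
    if (nrow(features) == 0) stop("empty feature set: distance is undefined")
    for (i in seq_len(nrow(features)))
      d <- pmin(d, sqrt((cc$x - features$x[i])^2 + (cc$y - features$y[i])^2))
  } else {
    if (is.matrix(features)) features <- list(features)
    if (length(features) == 0) stop("empty feature set: distance is undefined")
    for (ln in features) {
      for (s in seq_len(nrow(ln) - 1))
        d <- pmin(d, seg_dist(cc$x, cc$y, ln[s, 1], ln[s, 2],
                              ln[s + 1, 1], ln[s + 1, 2]))
    }
  }
  raster_grid(matrix(d, grid_nrow(template), grid_ncol(template)),
              xmin = template$xmin, ymin = template$ymin,
              cell_size = template$cell_size, crs = template$crs)
}

#' Feature density within a moving window
#'
#' Points (villages): count of points within `radius` of each cell center
#' divided by the geometric window area `pi * radius^2`, in points per km2.
#' Polylines (roads): total line length within the window divided by the
#' window area, in km per km2 (lines are chopped into sub-cell pieces and
#' accumulated by piece midpoint).
#'
#' @param features data.frame of points or list of polyline matrices.
#' @param radius window radius (m).
#' @param template [raster_grid()] defining the output geometry.
#' @return a [raster_grid()] of densities.
#' @export
feature_density <- function(features, radius, template) {
  if (radius <= 0) stop("radius must be positive")
  cs <- template$cell_size
  area_km2 <- pi * (radius / 1000)^2
  m <- matrix(0, grid_nrow(template), grid_ncol(template))
  if (is.data.frame(features)) {
    if (nrow(features) > 0) {
      rc <- grid_rowcol(template, features$x, features$y)
      for (i in seq_len(nrow(features)))
        if (!is.na(rc$row[i]))
          m[rc$row[i], rc$col[i]] <- m[rc$row[i], rc$col[i]] + 1
    }
    counts <- cpp_focal_stat(m, radius / cs, 1L)
    out <- counts / area_km2
  } else {
    if (is.matrix(features)) features <- list(features)
    for (ln in features) {
      for (s in seq_len(nrow(ln) - 1)) {
        x1 <- ln[s, 1]; y1 <- ln[s, 2]; x2 <- ln[s + 1, 1]; y2 <- ln[s + 1, 2]
        len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
        if (len == 0) next
        k <- max(1L, ceiling(len / (cs / 4)))
        t0 <- (seq_len(k) - 0.5) / k
        mx <- x1 + t0 * (x2 - x1); my <- y1 + t0 * (y2 - y1)
        rc <- grid_rowcol(template, mx, my)
        ok <- !is.na(rc$row)
        piece_km <- len / k / 1000
        for (i in which(ok))
          m[rc$row[i], rc$col[i]] <- m[rc$row[i], rc$col[i]] + piece_km
      }
    }
    out <- cpp_focal_stat(m, radius / cs, 1L) / area_km2
  }
  raster_grid(out, xmin = template$xmin, ymin = template$ymin,
              cell_size = cs, crs = template$crs)
}

# variable catalogue: 16 window-scalable variables + 3 distance variables
SCALABLE_VARS <- c("ELE", "SLP", "ASP", "TRI", "NPP", "BAM",
                   "AI", "ED", "PD", "SHDI",
                   "LPI_CNF", "PLAND_CNF", "LPI_CBF", "PLAND_CBF",
                   "Densvil", "Densrd")
DISTANCE_VARS <- c("Disvil", "Dismajor", "Disunpaved")

#' Build the multiscale covariate stack
#'
#' Assembles the full covariate vocabulary at every requested scale:
#' focal means of the continuous layers (`ELE`, `SLP`, `ASP`, `TRI`,
#' `NPP`, `BAM`), moving-window landscape metrics of the 7-class land
#' cover (`AI`, `ED`, `PD`, `SHDI` at landscape level; `LPI` and `PLAND`
#' for the closed needleleaf and closed broadleaf forest classes), village
#' and road densities (`Densvil`, `Densrd`), plus the unscaled Euclidean
#' distance layers (`Disvil`, `Dismajor`, `Disunpaved`). Layers are named
#' `VAR_scale` (e.g. `BAM_1000`); distance layers carry no scale suffix.
#'
#' @param base named list of aligned inputs: rasters `elevation`, `npp`,
#'   `bamboo`, `landcover`; data.frame `villages`; lists of polyline
#'   matrices `roads_major`, `roads_minor`. Only the inputs needed for the
#'   requested `vars` are required.
#' @param scales focal radii in meters, a subset of 1000-6000.
#' @param vars base variable names to build (default: all 19).
#' @param tpi_radius passed to [terrain_derivatives()].
#' @return a `covariate_stack`: list with `layers` (named list of
#'   [raster_grid()]), `scales`, `cell_size`.
#' @export
build_multiscale_stack <- function(base, scales = seq(1000, 6000, by = 1000),
                                   vars = c(SCALABLE_VARS, DISTANCE_VARS),
                                   tpi_radius = 750) {
  stopifnot(all(scales %in% seq(1000, 6000, by = 1000)))
  vars <- match.arg(vars, c(SCALABLE_VARS, DISTANCE_VARS),
                    several.ok = TRUE)
  rasters <- Filter(function(x) inherits(x, "raster_grid"), base)
  if (length(rasters) == 0)
    stop("base must contain at least one raster layer (grid template)")
  tmpl <- rasters[[1]]
  for (r in rasters) stop_unless_aligned(tmpl, r, "base layers")

  need_terrain <- any(c("SLP", "ASP", "TRI") %in% vars)
  td <- if (need_terrain) terrain_derivatives(base$elevation, tpi_radius)
  continuous <- list(ELE = base$elevation, NPP = base$npp, BAM = base$bamboo,
                     SLP = td$slope_position, ASP = td$trasp, TRI = td$tri)
  all_roads <- c(base$roads_major, base$roads_minor)

  layers <- list()
  for (v in intersect(vars, SCALABLE_VARS)) {
    for (s in scales) {
      nm <- paste0(v, "_", s)
      layers[[nm]] <-
        if (v %in% names(continuous)) {
          if (is.null(continuous[[v]])) stop(sprintf("base layer for %s missing", v))
          focal_mean(continuous[[v]], s)
        } else if (v == "Densvil") {
          feature_density(base$villages, s, tmpl)
        } else if (v == "Densrd") {
          feature_density(all_roads, s, tmpl)
        } else if (v %in% c("AI", "ED", "PD", "SHDI")) {
          window_metric(base$landcover, v, s)
        } else {
          cls <- if (grepl("CNF$", v)) LC_CNF else LC_CBF
          window_metric(base$landcover, sub("_(CNF|CBF)$", "", v), s,
                        level = "class", class = cls)
        }
    }
  }
  if ("Disvil" %in% vars)
    layers[["Disvil"]] <- distance_to_features(base$villages, tmpl)
  if ("Dismajor" %in% vars)
    layers[["Dismajor"]] <- distance_to_features(base$roads_major, tmpl)
  if ("Disunpaved" %in% vars)
    layers[["Disunpaved"]] <- distance_to_features(base$roads_minor, tmpl)

  structure(list(layers = layers, scales = scales,
                 cell_size = tmpl$cell_size),
            class = "covariate_stack")
}

#' @export
print.covariate_stack <- function(x, ...) {
  cat(sprintf("covariate_stack: %d layers at scales {%s} m\n",
              length(x$layers), paste(x$scales, collapse = ", ")))
  invisible(x)
}

#' Extract covariate values at point locations
#'
#' @param stack a `covariate_stack`.
#' @param points data.frame with `x`, `y`.
#' @param layers layer names to extract (default all).
#' @return data.frame, one column per layer.
#' @export
extract_covariates <- function(stack, points, layers = names(stack$layers)) {
  out <- lapply(stack$layers[layers], grid_extract, x = points$x, y = points$y)
  as.data.frame(out, check.names = FALSE)
}

#' Write / read a covariate stack as ESRI ASCII grids
#'
#' One `<layer>.asc` file per layer in `dir`; names round-trip.
#'
#' @param stack a `covariate_stack`.
#' @param dir directory.
#' @return `dir` (write) or a `covariate_stack` (read).
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(stack$layers))
    write_ascii_grid(stack$layers[[nm]], file.path(dir, paste0(nm, ".asc")))
  invisible(dir)
}

#' @rdname write_stack
#' @export
read_stack <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.asc$", full.names = TRUE))
  layers <- lapply(files, read_ascii_grid)
  names(layers) <- sub("\\.asc$", "", basename(files))
  scales <- sort(unique(as.numeric(stats::na.omit(
    suppressWarnings(as.numeric(sub("^.*_(\\d+)$", "\\1", names(layers))))))))
  structure(list(layers = layers, scales = scales,
                 cell_size = layers[[1]]$cell_size),
            class = "covariate_stack")
}
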