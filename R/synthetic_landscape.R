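#' Configuration for a synthetic mountain landscape
#'
#' Defines a seeded, fully reproducible synthetic landscape on a projected
#' 250-m grid: a smooth correlated terrain field, a binary bamboo layer
#' peaked in a mid-elevation band, villages and roads concentrated at low
#' elevation, and rectangular protected areas. The generated layers mirror
#' the covariate families used in montane panda habitat studies so that
#' every downstream stage (thinning, covariates, multiscale forests,
#' resistance, kernels) can be exercised against a known truth.
#'
#' @param seed integer master seed; identical config + seed gives
#'   bit-identical output.
#' @param nrow,ncol grid size in cells (at least 40 each).
#' @param cell_size cell edge in meters (default 250).
#' @param relief_amplitude standard deviation of the elevation field (m);
#'   0 gives a flat landscape at `base_elevation`.
#' @param relief_range terrain correlation length in cells (distance at
#'   which spatial autocorrelation of the regional component falls to
#'   1/e).
#' @param relief_detail fraction of terrain variance carried by a
#'   fine-scale roughness component (correlation length 3 cells), giving
#'   the field a massif-plus-valley spectrum.
#' @param base_elevation mean elevation (m).
#' @param n_villages,n_roads_major,n_roads_minor feature counts.
#' @param bamboo_band `c(low, high)` elevation band (m) where bamboo
#'   presence probability peaks.
#' @param pa_fraction approximate fraction of the extent covered by
#'   protected-area polygons (1 covers everything, 0 none).
#' @param village_elevation_bias place villages preferentially at low
#'   elevation?
#' @param n_occurrences presence points drawn from the true suitability
#'   surface. The default `NULL` scales a fixed occurrence density of
#'   0.06 points per km2 to the extent (floor 40): roughly twice the
#'   density of a mountain-range survey of 528 occurrences over 15,700
#'   km2, keeping balanced model datasets adequately powered on a
#'   desk-scale landscape while remaining feasible under the buffer and
#'   spacing constraints of pseudo-absence sampling.
#' @return a `landscape_config` list.
#' @export
landscape_config <- function(seed = 1, nrow = 100, ncol = 100,
                             cell_size = 250,
                             relief_amplitude = 900, relief_range = 20,
                             relief_detail = 0.35,
                             base_elevation = 2200,
                             n_villages = 210, n_roads_major = 2,
                             n_roads_minor = 3,
                             bamboo_band = c(2000, 3200),
                             pa_fraction = 0.3,
                             village_elevation_bias = TRUE,
                             n_occurrences = NULL) {
  if (nrow < 40 || ncol < 40)
    stop("degenerate extent: nrow and ncol must be at least 40 cells")
  if (cell_size <= 0) stop("cell_size must be positive")
  if (is.null(n_occurrences)) {
    area_km2 <- nrow * ncol * (cell_size / 1000)^2
    n_occurrences <- max(40L, round(0.06 * area_km2))
  }
  structure(as.list(environment()), class = "landscape_config")
}

# Periodic Gaussian random field: white noise convolved (via FFT) with a
# Gaussian kernel whose sd is range_cells / 2, so that the autocorrelation
# exp(-h^2 / range_cells^2) falls to 1/e at lag h = range_cells.
gaussian_field <- function(nr, nc, range_cells) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (range_cells <= 0) return(z)
  sigma <- range_cells / 2
  di <- 0:(nr - 1); di <- pmin(di, nr - di)
  dj <- 0:(nc - 1); dj <- pmin(dj, nc - dj)
  K <- exp(-outer(di^2, dj^2, "+") / (2 * sigma^2))
  K <- K / sum(K)
  s <- Re(stats::fft(stats::fft(z) * stats::fft(K), inverse = TRUE)) / (nr * nc)
  s
}

#' Generate the synthetic elevation field
#'
#' A spectrally filtered Gaussian random field standardized to the
#' configured relief amplitude, centered on `base_elevation` and clamped to
#' a plausible montane range (500-5,000 m).
#'
#' @param config a [landscape_config()].
#' @return elevation [raster_grid()] (m).
#' @export
generate_terrain <- function(config) {
  with_seed(config$seed + 1L, {
    f <- gaussian_field(config$nrow, config$ncol, config$relief_range)
    det <- config$relief_detail %||% 0
    if (det > 0) {
      std <- function(m) if (stats::sd(m) > 0) (m - mean(m)) / stats::sd(m) else m
      fine <- gaussian_field(config$nrow, config$ncol, 3)
      f <- sqrt(1 - det) * std(f) + sqrt(det) * std(fine)
    }
    if (config$relief_amplitude > 0) {
      f <- (f - mean(f)) / stats::sd(f)
      elev <- config$base_elevation + config$relief_amplitude * f
    } else {
      elev <- matrix(config$base_elevation, config$nrow, config$ncol)
    }
    elev <- pmin(pmax(elev, 500), 5000)
    raster_grid(elev, cell_size = config$cell_size)
  })
}

#' Generate the binary bamboo layer
#'
#' Bernoulli presence with probability peaked inside the configured
#' elevation band (falling off smoothly outside it) and modulated by a
#' smooth stand-patchiness field with a sub-kilometre correlation length
#' (bamboo grows in discrete stands, not as a uniform carpet), then
#' majority-smoothed over 3x3 neighborhoods to produce contiguous stands.
#'
#' @param config a [landscape_config()].
#' @param terrain elevation raster from [generate_terrain()].
#' @return binary (0/1) [raster_grid()].
#' @export
generate_bamboo <- function(config, terrain) {
  with_seed(config$seed + 2L, {
    elev <- terrain$values
    patch <- gaussian_field(nrow(elev), ncol(elev), 3)
    patch <- if (stats::sd(patch) > 0) (patch - mean(patch)) / stats::sd(patch)
      else patch
    lo <- config$bamboo_band[1]; hi <- config$bamboo_band[2]
    d <- pmax(lo - elev, 0) + pmax(elev - hi, 0)  # distance outside the band
    p <- 0.9 * exp(-0.5 * (d / 150)^2) * stats::plogis(1.8 * patch)
    bam <- matrix(stats::rbinom(length(p), 1, as.vector(p)),
                  nrow(p), ncol(p))
    sm <- cpp_focal_stat(bam * 1.0, 1.5, 0L)  # 3x3 majority filter
    out <- ifelse(sm >= 0.5, 1, 0)
    raster_grid(out, xmin = terrain$xmin, ymin = terrain$ymin,
                cell_size = terrain$cell_size, crs = terrain$crs)
  })
}

#' Generate a synthetic net-primary-productivity layer
#'
#' Productivity declines with elevation and carries smooth seeded noise;
#' a stand-in for satellite NPP products.
#'
#' @param config a [landscape_config()].
#' @param terrain elevation raster.
#' @return NPP [raster_grid()] (gC m-2 yr-1 scale).
#' @export
generate_npp <- function(config, terrain) {
  with_seed(config$seed + 5L, {
    elev <- terrain$values
    base <- 900 * exp(-0.5 * ((elev - 1500) / 1400)^2)
    noise <- gaussian_field(nrow(elev), ncol(elev), 5)
    noise <- if (stats::sd(noise) > 0) (noise - mean(noise)) / stats::sd(noise) else noise
    raster_grid(pmax(base + 60 * noise, 0), xmin = terrain$xmin,
                ymin = terrain$ymin, cell_size = terrain$cell_size,
                crs = terrain$crs)
  })
}

#' Generate a 7-class land-cover layer
#'
#' Classes follow the montane vegetation-zone ordering used for reclassified
#' global land-cover products: 1 crop, 2 shrub, 3 grass, 4 closed broadleaf
#' forest (CBF), 5 closed needleleaf forest (CNF), 6 open forest (OF),
#' 7 non-vegetation. Assignment is by elevation zone with seeded
#' class noise.
#'
#' @param config a [landscape_config()].
#' @param terrain elevation raster.
#' @return categorical [raster_grid()] with integer codes 1-7.
#' @export
generate_landcover <- function(config, terrain) {
  with_seed(config$seed + 4L, {
    elev <- as.vector(terrain$values)
    cls <- integer(length(elev))
    cls[elev < 1600] <- 1                       # crop / settled valley floor
    cls[elev >= 1600 & elev < 2000] <- 4        # broadleaf forest
    cls[elev >= 2000 & elev < 2600] <-
      ifelse(stats::runif(sum(elev >= 2000 & elev < 2600)) < 0.5, 4, 5)
    cls[elev >= 2600 & elev < 3600] <- 5        # needleleaf forest
    cls[elev >= 3600 & elev < 4100] <- 2        # shrub
    cls[elev >= 4100 & elev < 4400] <- 3        # alpine meadow
    cls[elev >= 4400] <- 7                      # scree / snow
    # speckle: open forest and random class noise
    n <- length(cls)
    flip <- stats::runif(n)
    cls[flip < 0.10 & cls %in% c(4, 5)] <- 6
    noisy <- flip > 0.92
    cls[noisy] <- sample(1:7, sum(noisy), replace = TRUE)
    raster_grid(matrix(as.numeric(cls), grid_nrow(terrain), grid_ncol(terrain)),
                xmin = terrain$xmin, ymin = terrain$ymin,
                cell_size = terrain$cell_size, crs = terrain$crs)
  })
}

#' Generate villages, roads and protected areas
#'
#' Villages form compact settlements: settlement centers are drawn with a
#' low-elevation bias under a 7-km inhibition distance (villages
#' agglomerate in valleys, and neighboring settlements keep apart), and
#' roughly six villages scatter within 300 m of each center. Roads are
#' jittered polylines crossing the extent, split into major and minor
#' classes; protected areas are rectangles accumulated until they cover
#' approximately `pa_fraction` of the extent.
#'
#' @param config a [landscape_config()].
#' @param terrain elevation raster.
#' @return a `landscape_features` list with elements `villages`
#'   (data.frame x, y), `roads` (list of coordinate matrices), `road_class`
#'   (character, "major"/"minor"), `protected_areas` (list of closed
#'   polygon matrices).
#' @export
generate_features <- function(config, terrain) {
  with_seed(config$seed + 3L, {
    cs <- terrain$cell_size
    W <- grid_ncol(terrain) * cs
    H <- grid_nrow(terrain) * cs
    cc <- grid_cell_centers(terrain)

    villages <- if (config$n_villages > 0) {
      w <- if (config$village_elevation_bias)
        exp(-(cc$value - min(cc$value)) / 500) else rep(1, nrow(cc))
      n_settle <- max(1L, round(config$n_villages / 6))
      ord <- sample.int(nrow(cc), prob = w)
      ctr_x <- numeric(0); ctr_y <- numeric(0)
      for (i in ord) {
        if (length(ctr_x) == 0 ||
            min(sqrt((cc$x[i] - ctr_x)^2 + (cc$y[i] - ctr_y)^2)) > 7000) {
          ctr_x <- c(ctr_x, cc$x[i]); ctr_y <- c(ctr_y, cc$y[i])
        }
        if (length(ctr_x) >= n_settle) break
      }
      per <- ceiling(config$n_villages / length(ctr_x))
      nv <- per * length(ctr_x)
      vx <- rep(ctr_x, each = per) + stats::rnorm(nv, 0, 300)
      vy <- rep(ctr_y, each = per) + stats::rnorm(nv, 0, 300)
      data.frame(
        x = pmin(pmax(vx, terrain$xmin + cs / 100),
                 terrain$xmin + W - cs / 100),
        y = pmin(pmax(vy, terrain$ymin + cs / 100),
                 terrain$ymin + H - cs / 100)
      )[seq_len(min(nv, config$n_villages)), ]
    } else data.frame(x = numeric(0), y = numeric(0))

    n_roads <- config$n_roads_major + config$n_roads_minor
    roads <- vector("list", n_roads)
    road_class <- character(n_roads)
    for (i in seq_len(n_roads)) {
      horiz <- (i %% 2 == 0)
      nv <- 9
      t <- seq(0, 1, length.out = nv)
      if (horiz) {
        y0 <- stats::runif(1, 0.15, 0.85) * H
        y1 <- stats::runif(1, 0.15, 0.85) * H
        x <- terrain$xmin + t * W
        y <- terrain$ymin + y0 + t * (y1 - y0)
        y <- pmin(pmax(y + c(0, stats::rnorm(nv - 2, 0, H / 30), 0),
                       terrain$ymin), terrain$ymin + H)
      } else {
        x0 <- stats::runif(1, 0.15, 0.85) * W
        x1 <- stats::runif(1, 0.15, 0.85) * W
        y <- terrain$ymin + t * H
        x <- terrain$xmin + x0 + t * (x1 - x0)
        x <- pmin(pmax(x + c(0, stats::rnorm(nv - 2, 0, W / 30), 0),
                       terrain$xmin), terrain$xmin + W)
      }
      roads[[i]] <- cbind(x = x, y = y)
      road_class[i] <- if (i <= config$n_roads_major) "major" else "minor"
    }

    pas <- list()
    if (config$pa_fraction >= 1) {
      pas[[1]] <- rect_poly(terrain$xmin, terrain$ymin,
                            terrain$xmin + W, terrain$ymin + H)
    } else if (config$pa_fraction > 0) {
      covered <- rep(FALSE, nrow(cc))
      for (k in 1:100) {
        w <- stats::runif(1, 0.15, 0.35) * W
        h <- stats::runif(1, 0.15, 0.35) * H
        x0 <- terrain$xmin + stats::runif(1, 0, W - w)
        y0 <- terrain$ymin + stats::runif(1, 0, H - h)
        pas[[length(pas) + 1]] <- rect_poly(x0, y0, x0 + w, y0 + h)
        covered <- covered | (cc$x >= x0 & cc$x <= x0 + w &
                                cc$y >= y0 & cc$y <= y0 + h)
        if (mean(covered) >= config$pa_fraction) break
      }
    }

    structure(list(villages = villages, roads = roads,
                   road_class = road_class, protected_areas = pas),
              class = "landscape_features")
  })
}

rect_poly <- function(x0, y0, x1, y1) {
  cbind(x = c(x0, x1, x1, x0, x0), y = c(y0, y0, y1, y1, y0))
}

#' Raster of village counts per cell
#'
#' @param features a `landscape_features` object.
#' @param template [raster_grid()] defining the geometry.
#' @return [raster_grid()] of point counts.
#' @export
village_count_raster <- function(features, template) {
  m <- matrix(0, grid_nrow(template), grid_ncol(template))
  v <- features$villages
  if (nrow(v) > 0) {
    rc <- grid_rowcol(template, v$x, v$y)
    ok <- !is.na(rc$row)
    for (i in which(ok)) m[rc$row[i], rc$col[i]] <- m[rc$row[i], rc$col[i]] + 1
  }
  raster_grid(m, xmin = template$xmin, ymin = template$ymin,
              cell_size = template$cell_size, crs = template$crs)
}

#' Known generative suitability model
#'
#' A logistic model over scale-specific focal means of named base layers.
#' Each term is a list with `layer` (base-layer name), `scale` (focal
#' radius, m, one of 1000-6000), `shape` (`"linear"` or `"unimodal"`),
#' `coef`, and for unimodal terms `optimum` and `width` (in the layer's
#' units). The linear predictor is squashed through `plogis`, so the true
#' suitability lies in \[0, 1\] everywhere.
#'
#' @param terms list of term lists (see above).
#' @param intercept intercept of the linear predictor.
#' @return a `true_suitability_model`.
#' @export
true_suitability_model <- function(terms, intercept = 0) {
  scales_ok <- seq(1000, 6000, by = 1000)
  for (tm in terms) {
    stopifnot(is.character(tm$layer),
              tm$shape %in% c("linear", "unimodal"))
    if (!tm$scale %in% scales_ok)
      stop("term scale must belong to the study scale set 1000-6000 m")
    if (tm$shape == "unimodal" && (is.null(tm$optimum) || is.null(tm$width)))
      stop("unimodal terms need optimum and width")
  }
  structure(list(terms = terms, intercept = intercept),
            class = "true_suitability_model")
}

#' Default generative model: fine-scale biotic terms, coarse-scale
#' anthropogenic term
#'
#' Unimodal elevation effect (optimum 2,600 m) and positive bamboo effect
#' both at the 1-km scale, and a negative village-density effect (per
#' km2, via [feature_density()]) at the 4-km scale, so that
#' scale-recovery tests target a mixture of fine and coarse generative
#' scales.
#'
#' @return a [true_suitability_model()].
#' @export
default_suitability_model <- function() {
  true_suitability_model(
    terms = list(
      list(layer = "elevation", scale = 1000, shape = "unimodal",
           coef = 7, optimum = 2600, width = 300),
      list(layer = "bamboo", scale = 1000, shape = "linear", coef = 4.5),
      list(layer = "villages", scale = 4000, shape = "linear",
           coef = -40)
    ),
    intercept = -7
  )
}

#' Evaluate a true suitability model on base layers
#'
#' Raster terms are aggregated as the focal mean of the base layer within
#' the term's scale radius; point-feature terms (a data.frame of `x`, `y`)
#' are aggregated as the feature density within that radius
#' ([feature_density()]), so generative terms use exactly the same
#' windowed quantities as the downstream covariate engine.
#'
#' @param model a [true_suitability_model()].
#' @param layers named list of aligned [raster_grid()] base layers (or
#'   point-feature data.frames); every `layer` named by a model term must
#'   be present.
#' @return suitability [raster_grid()] with values in \[0, 1\].
#' @export
evaluate_suitability <- function(model, layers) {
  stopifnot(inherits(model, "true_suitability_model"))
  tmpl <- Filter(function(x) inherits(x, "raster_grid"), layers)[[1]]
  eta <- matrix(model$intercept, grid_nrow(tmpl), grid_ncol(tmpl))
  for (tm in model$terms) {
    base <- layers[[tm$layer]]
    if (is.null(base)) stop(sprintf("base layer '%s' missing", tm$layer))
    if (is.data.frame(base)) {
      fm <- feature_density(base, tm$scale, tmpl)$values
    } else {
      stop_unless_aligned(tmpl, base, "model base layers")
      fm <- focal_mean(base, tm$scale)$values
    }
    contrib <- switch(tm$shape,
      linear = tm$coef * fm,
      unimodal = tm$coef * exp(-0.5 * ((fm - tm$optimum) / tm$width)^2)
    )
    eta <- eta + contrib
  }
  raster_grid(stats::plogis(eta), xmin = tmpl$xmin, ymin = tmpl$ymin,
              cell_size = tmpl$cell_size, crs = tmpl$crs)
}

#' Sample presence points from a suitability surface
#'
#' Draws `n` distinct cells with probability proportional to suitability
#' (cells with zero or nodata suitability are never drawn) and jitters each
#' point uniformly within its cell.
#'
#' @param suitability [raster_grid()] with values in \[0, 1\].
#' @param n number of presence points.
#' @param seed integer seed.
#' @return data.frame `x`, `y`, `label = "presence"`.
#' @export
sample_occurrences <- function(suitability, n = 528, seed = 1) {
  cc <- grid_cell_centers(suitability)
  ok <- which(!is.na(cc$value) & cc$value > 0)
  if (n > length(ok))
    stop(sprintf(
      "requested %d occurrences but only %d cells have positive suitability",
      n, length(ok)))
  with_seed(seed, {
    idx <- ok[sample.int(length(ok), n, prob = cc$value[ok])]
    cs <- suitability$cell_size
    data.frame(
      x = cc$x[idx] + stats::runif(n, -0.5, 0.5) * cs,
      y = cc$y[idx] + stats::runif(n, -0.5, 0.5) * cs,
      label = "presence"
    )
  })
}

#' Generate a complete synthetic landscape
#'
#' One-stop constructor: terrain, bamboo, NPP, land cover, vector features,
#' the generative suitability model evaluated on the landscape, and
#' presence points sampled from it.
#'
#' @param config a [landscape_config()].
#' @param model a [true_suitability_model()]; default
#'   [default_suitability_model()].
#' @return list with elements `config`, `terrain`, `bamboo`, `npp`,
#'   `landcover`, `features`, `village_count`, `model`, `suitability`,
#'   `occurrences`.
#' @export
synthetic_landscape <- function(config = landscape_config(),
                                model = default_suitability_model()) {
  terrain <- generate_terrain(config)
  bamboo <- generate_bamboo(config, terrain)
  npp <- generate_npp(config, terrain)
  landcover <- generate_landcover(config, terrain)
  features <- generate_features(config, terrain)
  vc <- village_count_raster(features, terrain)
  suit <- evaluate_suitability(
    model, list(elevation = terrain, bamboo = bamboo,
                villages = features$villages, village_count = vc))
  occ <- sample_occurrences(suit, n = config$n_occurrences,
                            seed = config$seed + 7L)
  list(config = config, terrain = terrain, bamboo = bamboo, npp = npp,
       landcover = landcover, features = features, village_count = vc,
       model = model, suitability = suit, occurrences = occ)
}

#' Write vector features to GeoJSON
#'
#' Villages become Point features, roads LineString features (with a
#' `class` property), protected areas Polygon features.
#'
#' @param features a `landscape_features` object.
#' @param path output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_features_geojson <- function(features, path) {
  feats <- list()
  v <- features$villages
  for (i in seq_len(nrow(v))) {
    feats[[length(feats) + 1]] <- list(
      type = "Feature", properties = list(kind = "village"),
      geometry = list(type = "Point",
                      coordinates = c(v$x[i], v$y[i])))
  }
  for (i in seq_along(features$roads)) {
    feats[[length(feats) + 1]] <- list(
      type = "Feature",
      properties = list(kind = "road", class = features$road_class[i]),
      geometry = list(type = "LineString",
                      coordinates = unname(features$roads[[i]])))
  }
  for (i in seq_along(features$protected_areas)) {
    feats[[length(feats) + 1]] <- list(
      type = "Feature", properties = list(kind = "protected_area"),
      geometry = list(type = "Polygon",
                      coordinates = list(unname(features$protected_areas[[i]]))))
  }
  json <- jsonlite::toJSON(list(type = "FeatureCollection", features = feats),
                           auto_unbox = TRUE, digits = NA)
  writeLines(json, path)
  invisible(path)
}
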