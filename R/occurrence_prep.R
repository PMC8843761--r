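#' Spatially thin occurrence points
#'
#' Enforces a minimum pairwise distance between retained points, the
#' standard pre-processing step for survey occurrences that reduces spatial
#' autocorrelation (default radius 1,200 m, the scale of an average panda
#' home range). The rule is greedy: while any pair lies closer than
#' `radius`, remove the point with the most neighbors within `radius`,
#' breaking ties by removing the lowest point index. The result is maximal:
#' no removed point could be added back without violating the radius.
#'
#' @param points data.frame with columns `x`, `y` in projected meters.
#' @param radius minimum pairwise distance (m).
#' @return the retained subset of `points` (row order preserved), with the
#'   attribute `n_removed`.
#' @export
thin_occurrences <- function(points, radius = 1200) {
  if (radius <= 0) stop("radius must be positive")
  n <- nrow(points)
  if (n == 0) return(points)
  d <- as.matrix(stats::dist(points[, c("x", "y")]))
  close <- d < radius
  diag(close) <- FALSE
  keep <- rep(TRUE, n)
  repeat {
    nb <- rowSums(close[keep, keep, drop = FALSE])
    if (all(nb == 0)) break
    worst <- which(keep)[which.max(nb)]  # which.max takes the lowest index on ties
    keep[worst] <- FALSE
  }
  out <- points[keep, , drop = FALSE]
  attr(out, "n_removed") <- n - sum(keep)
  out
}

#' Constraints for pseudo-absence generation
#'
#' Defaults follow the geographically stratified scheme used for panda
#' surveys: pseudo-absences must lie outside a 3-km buffer around every
#' presence (maximum territory scale), below 4,000 m elevation, on slopes
#' below 50 degrees, at least 1.2 km apart from one another, drawn as ten
#' independent sets of the same size as the presences.
#'
#' @param exclusion_radius buffer radius around presences (m).
#' @param max_elevation maximum elevation (m).
#' @param max_slope maximum slope (degrees).
#' @param min_spacing minimum within-set spacing (m).
#' @param n_sets number of replicate pseudo-absence sets.
#' @param max_attempts rejection-sampling cap per point.
#' @return an `absence_constraints` list.
#' @export
absence_constraints <- function(exclusion_radius = 3000,
                                max_elevation = 4000,
                                max_slope = 50,
                                min_spacing = 1200,
                                n_sets = 10,
                                max_attempts = 10000) {
  stopifnot(exclusion_radius > 0, max_elevation > 0, max_slope > 0,
            min_spacing > 0, n_sets >= 1)
  structure(as.list(environment()), class = "absence_constraints")
}

#' Generate constrained pseudo-absence sets
#'
#' Rejection sampling over eligible raster cells (below the elevation and
#' slope caps and outside the presence exclusion buffer), with a uniform
#' jitter within the cell and a sequential within-set spacing check. Each
#' set contains exactly as many points as there are presences.
#'
#' @param presences data.frame `x`, `y` of presence points.
#' @param constraints an [absence_constraints()].
#' @param dem elevation [raster_grid()] (m).
#' @param slope slope [raster_grid()] (degrees), aligned with `dem`.
#' @param seed integer seed; set `s` uses `seed + s`.
#' @return list of `n_sets` data.frames with columns `x`, `y`,
#'   `label = "pseudo_absence"`, `replicate_id`.
#' @export
generate_pseudo_absences <- function(presences, constraints, dem, slope,
                                     seed = 1) {
  stopifnot(inherits(constraints, "absence_constraints"))
  stop_unless_aligned(dem, slope, "dem and slope")
  n <- nrow(presences)
  cc <- grid_cell_centers(dem)
  ok_elev <- !is.na(cc$value) & cc$value < constraints$max_elevation
  slp <- grid_extract(slope, cc$x, cc$y)
  ok_slope <- !is.na(slp) & slp < constraints$max_slope

  # distance from each cell center to the nearest presence
  dmin <- rep(Inf, nrow(cc))
  for (i in seq_len(n)) {
    di <- sqrt((cc$x - presences$x[i])^2 + (cc$y - presences$y[i])^2)
    dmin <- pmin(dmin, di)
  }
  ok_buffer <- dmin > constraints$exclusion_radius
  eligible <- which(ok_elev & ok_slope & ok_buffer)
  if (length(eligible) == 0) {
    binding <- if (!any(ok_elev)) "max_elevation"
      else if (!any(ok_elev & ok_slope)) "max_slope"
      else "exclusion_radius"
    stop(sprintf("no eligible cells for pseudo-absences (binding constraint: %s)",
                 binding))
  }
  if (length(eligible) < n)
    stop(sprintf(
      "only %d eligible cells for %d pseudo-absences (binding constraint: exclusion_radius/max_elevation/max_slope jointly)",
      length(eligible), n))

  cs <- dem$cell_size
  lapply(seq_len(constraints$n_sets), function(s) {
    with_seed(seed + s, {
      pool <- sample(eligible)  # random cell order for this set
      ax <- numeric(n); ay <- numeric(n)
      got <- 0L; attempts <- 0L; k <- 0L
      while (got < n) {
        attempts <- attempts + 1L
        if (attempts > constraints$max_attempts * n)
          stop(sprintf(
            "could not place %d pseudo-absences after %d attempts (binding constraint: min_spacing)",
            n, attempts))
        k <- k + 1L
        if (k > length(pool)) { k <- 1L; pool <- sample(eligible) }
        i <- pool[k]
        px <- cc$x[i] + stats::runif(1, -0.5, 0.5) * cs
        py <- cc$y[i] + stats::runif(1, -0.5, 0.5) * cs
        # jitter must not re-enter the presence buffer
        if (min(sqrt((presences$x - px)^2 + (presences$y - py)^2)) <=
            constraints$exclusion_radius) next
        if (got > 0 &&
            min(sqrt((ax[seq_len(got)] - px)^2 +
                     (ay[seq_len(got)] - py)^2)) < constraints$min_spacing)
          next
        got <- got + 1L
        ax[got] <- px; ay[got] <- py
      }
      data.frame(x = ax, y = ay, label = "pseudo_absence",
                 replicate_id = s)
    })
  })
}

#' Read / write occurrence CSV
#'
#' Column layout `x`, `y`, `label`, `replicate_id` (the replicate id is 0
#' for presences).
#'
#' @param occ data.frame of occurrences.
#' @param path CSV path.
#' @return `path` (write) or data.frame (read).
#' @export
write_occurrences <- function(occ, path) {
  if (is.null(occ$replicate_id)) occ$replicate_id <- 0L
  utils::write.csv(occ[, c("x", "y", "label", "replicate_id")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_occurrences
#' @export
read_occurrences <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
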