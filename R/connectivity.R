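#' Build the cost graph of a resistance raster
#'
#' Valid (non-nodata) cells are graph nodes; 8-neighbor adjacencies are
#' edges weighted by the mean of the two cells' resistance times the
#' center-to-center distance in meters (x sqrt(2) on diagonals). With
#' uniform resistance 1 an edge weight equals the geometric distance, which
#' calibrates the cost unit: 1 cost unit = 1 meter traversed at minimal
#' resistance.
#'
#' @param resistance [raster_grid()] of resistance values (> 0).
#' @param connectivity 8 (default) or 4.
#' @return a `cost_graph`: list with the igraph `graph` (vertex ids =
#'   linear cell indices in column-major matrix order), `template`, and
#'   `valid` mask.
#' @export
cost_graph <- function(resistance, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  v <- resistance$values
  if (any(v[!is.na(v)] <= 0)) stop("resistance values must be positive")
  nr <- nrow(v); nc <- ncol(v)
  cs <- resistance$cell_size
  idx <- matrix(seq_len(nr * nc), nr, nc)

  edge_set <- function(dr, dc) {
    r1 <- if (dr >= 0) 1:(nr - dr) else (1 - dr):nr
    c1 <- if (dc >= 0) 1:(nc - dc) else (1 - dc):nc
    a <- as.vector(idx[r1, c1, drop = FALSE])
    b <- as.vector(idx[r1 + dr, c1 + dc, drop = FALSE])
    w <- (v[a] + v[b]) / 2 * cs * sqrt(dr^2 + dc^2)
    ok <- !is.na(w)
    cbind(a[ok], b[ok], w[ok])
  }
  offs <- list(c(0, 1), c(1, 0))
  if (connectivity == 8) offs <- c(offs, list(c(1, 1), c(1, -1)))
  ed <- do.call(rbind, lapply(offs, function(o) edge_set(o[1], o[2])))
  g <- igraph::make_graph(as.vector(t(ed[, 1:2])), n = nr * nc,
                          directed = FALSE)
  igraph::E(g)$weight <- ed[, 3]
  structure(list(graph = g, template = resistance,
                 valid = !is.na(v)),
            class = "cost_graph")
}

points_to_cells <- function(template, sources) {
  rc <- grid_rowcol(template, sources$x, sources$y)
  bad <- is.na(rc$row)
  if (any(bad))
    stop(sprintf("source point(s) outside the raster extent: %s",
                 paste(which(bad), collapse = ", ")))
  cells <- (rc$col - 1) * nrow(template$values) + rc$row
  nod <- is.na(template$values[cbind(rc$row, rc$col)])
  if (any(nod))
    stop(sprintf("source point(s) on nodata cells: %s",
                 paste(which(nod), collapse = ", ")))
  cells
}

as_cost_graph <- function(x) {
  if (inherits(x, "cost_graph")) x else cost_graph(x)
}

#' Accumulated cost distance from source points
#'
#' Dijkstra's algorithm on the 8-neighbor cost graph. Costs beyond
#' `max_cost` are set to `Inf` (unreached); the cost at each source cell
#' is 0.
#'
#' @param resistance [raster_grid()] or a prebuilt [cost_graph()].
#' @param sources data.frame `x`, `y` of source points (on valid cells).
#' @param max_cost truncation threshold in cost units (default `Inf`).
#' @return matrix (sources x cells) of accumulated costs; attribute
#'   `cells` holds the source cell indices.
#' @export
cost_distance <- function(resistance, sources, max_cost = Inf) {
  if (max_cost <= 0) stop("max_cost must be positive")
  cg <- as_cost_graph(resistance)
  cells <- points_to_cells(cg$template, sources)
  d <- igraph::distances(cg$graph, v = cells, algorithm = "dijkstra")
  d[, !cg$valid] <- Inf
  d[d > max_cost] <- Inf
  attr(d, "cells") <- cells
  d
}

#' Resistant dispersal kernel surface
#'
#' Around every source the dispersal kernel decays with accumulated cost:
#' linearly, `k = max(0, 1 - cost / threshold)` (the standard resistant-
#' kernel form), or as a Gaussian with the threshold at 3 sd, truncated at
#' the threshold. Summing over sources gives the expected density of
#' dispersers; an isolated source cell scores exactly 1.
#'
#' @param resistance [raster_grid()] or [cost_graph()].
#' @param sources data.frame `x`, `y` of source points.
#' @param threshold dispersal-cost threshold (cost units), e.g. 6000,
#'   12000, 20000.
#' @param shape `"linear"` (default) or `"gaussian"`.
#' @param chunk sources processed per Dijkstra call (memory control).
#' @return a `kernel_surface` [raster_grid()] with attributes `threshold`
#'   and `n_sources`.
#' @export
resistant_kernel <- function(resistance, sources, threshold,
                             shape = c("linear", "gaussian"), chunk = 64) {
  shape <- match.arg(shape)
  if (nrow(sources) == 0) stop("no source points")
  stopifnot(threshold > 0)
  cg <- as_cost_graph(resistance)
  tmpl <- cg$template
  acc <- numeric(length(tmpl$values))
  for (start in seq(1, nrow(sources), by = chunk)) {
    sub <- sources[start:min(start + chunk - 1, nrow(sources)), , drop = FALSE]
    d <- cost_distance(cg, sub, max_cost = threshold)
    k <- if (shape == "linear") pmax(1 - d / threshold, 0)
      else exp(-0.5 * (3 * d / threshold)^2) * (d <= threshold)
    k[!is.finite(d)] <- 0
    k <- matrix(k, nrow = nrow(d))
    acc <- acc + colSums(k)
  }
  acc[!cg$valid] <- NA_real_
  out <- raster_grid(matrix(acc, nrow(tmpl$values), ncol(tmpl$values)),
                     xmin = tmpl$xmin, ymin = tmpl$ymin,
                     cell_size = tmpl$cell_size, crs = tmpl$crs)
  attr(out, "threshold") <- threshold
  attr(out, "n_sources") <- nrow(sources)
  class(out) <- c("kernel_surface", class(out))
  out
}

#' Least-cost path between two points
#'
#' Minimal-cost 8-connected cell sequence from `a` to `b` (Dijkstra); the
#' path cost equals the accumulated cost distance between the two cells.
#'
#' @param resistance [raster_grid()] or [cost_graph()].
#' @param a,b data.frames (or lists) with single `x`, `y` points.
#' @return list with `cells` (linear indices), `coords` (data.frame), and
#'   `cost`.
#' @export
least_cost_path <- function(resistance, a, b) {
  cg <- as_cost_graph(resistance)
  ca <- points_to_cells(cg$template, as.data.frame(a))
  cb <- points_to_cells(cg$template, as.data.frame(b))
  if (ca == cb) {
    cells <- ca
    cost <- 0
  } else {
    sp <- igraph::shortest_paths(cg$graph, from = ca, to = cb,
                                 output = "vpath")
    cells <- as.integer(sp$vpath[[1]])
    if (length(cells) == 0) return(list(cells = integer(0),
                                        coords = NULL, cost = Inf))
    cost <- igraph::distances(cg$graph, v = ca, to = cb)[1, 1]
  }
  nr <- nrow(cg$template$values)
  row <- (cells - 1) %% nr + 1
  col <- (cells - 1) %/% nr + 1
  coords <- data.frame(
    x = cg$template$xmin + (col - 0.5) * cg$template$cell_size,
    y = grid_ymax(cg$template) - (row - 0.5) * cg$template$cell_size)
  list(cells = cells, coords = coords, cost = cost)
}

# separable Gaussian blur with a unit-sum kernel (mass-preserving away
# from the raster edge); NA cells carry zero mass
gaussian_blur <- function(m, sigma_cells) {
  if (sigma_cells <= 0) return(m)
  h <- max(1L, ceiling(3 * sigma_cells))
  k <- exp(-0.5 * ((-h:h) / sigma_cells)^2)
  k <- k / sum(k)
  conv1 <- function(x) {
    xp <- c(numeric(h), x, numeric(h))
    out <- stats::filter(xp, k, sides = 2)
    as.numeric(out[(h + 1):(h + length(x))])
  }
  m[is.na(m)] <- 0
  m <- apply(m, 2, conv1)
  t(apply(t(m), 2, conv1))
}

#' Factorial least-cost-path corridor density
#'
#' Computes least-cost paths between all unordered pairs of source points
#' whose path cost does not exceed `max_cost`, rasterizes each path as a
#' unit indicator over its cells, convolves it with a unit-sum 2-D
#' Gaussian (kernel-density buffering), and sums the contributions. Pixel
#' values therefore count the least-cost paths passing through (near) the
#' pixel; with bandwidth 0 the support is exactly the union of raw path
#' cells.
#'
#' @param resistance [raster_grid()] or [cost_graph()].
#' @param sources data.frame `x`, `y` of at least two source points.
#' @param max_cost upper dispersal limit in cost units (default 50000).
#' @param bandwidth Gaussian buffering sd in cells (default 2).
#' @return a `corridor_density` [raster_grid()] with attributes `n_paths`,
#'   `n_pairs`, `bandwidth`, `max_cost`.
#' @export
factorial_lcp_density <- function(resistance, sources, max_cost = 50000,
                                  bandwidth = 2) {
  if (nrow(sources) < 2) stop("need at least two source points")
  cg <- as_cost_graph(resistance)
  tmpl <- cg$template
  cells <- points_to_cells(tmpl, sources)
  n <- length(cells)
  acc <- matrix(0, nrow(tmpl$values), ncol(tmpl$values))
  pc <- igraph::distances(cg$graph, v = cells, to = cells,
                          algorithm = "dijkstra")
  n_paths <- 0L
  for (i in seq_len(n - 1)) {
    to <- which(pc[i, ] <= max_cost)
    to <- to[to > i & cells[to] != cells[i]]
    if (length(to) == 0) next
    sps <- igraph::shortest_paths(cg$graph, from = cells[i],
                                  to = cells[to], output = "vpath")
    for (p in sps$vpath) {
      pcells <- as.integer(p)
      if (length(pcells) == 0) next
      path_m <- matrix(0, nrow(acc), ncol(acc))
      path_m[pcells] <- 1
      acc <- acc + path_m
      n_paths <- n_paths + 1L
    }
  }
  if (n_paths == 0) warning("no source pair is reachable within max_cost")
  if (bandwidth > 0 && n_paths > 0) acc <- gaussian_blur(acc, bandwidth)
  acc[!cg$valid] <- NA_real_
  out <- raster_grid(acc, xmin = tmpl$xmin, ymin = tmpl$ymin,
                     cell_size = tmpl$cell_size, crs = tmpl$crs)
  attr(out, "n_paths") <- n_paths
  attr(out, "n_pairs") <- n * (n - 1) / 2
  attr(out, "bandwidth") <- bandwidth
  attr(out, "max_cost") <- max_cost
  class(out) <- c("corridor_density", class(out))
  out
}
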