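#' Extract core habitat patches from a kernel surface
#'
#' Core habitat is defined as contiguous area where the summed resistant-
#' kernel value exceeds a fraction (default 5%) of the surface maximum.
#' Cells strictly greater than the cutoff are kept and labeled into
#' maximal 8-connected patches.
#'
#' @param kernel a kernel-surface [raster_grid()].
#' @param fraction cutoff as a fraction of the maximum (default 0.05).
#' @param connectivity 8 (default) or 4.
#' @return a `patch_set`: list with `labels` ([raster_grid()] of integer
#'   patch ids, 0 outside), `patches` (data.frame `id`, `cells`,
#'   `area_km2`), `total_km2`, `cutoff` (absolute threshold value),
#'   `fraction`.
#' @export
extract_core_patches <- function(kernel, fraction = 0.05, connectivity = 8) {
  stopifnot(fraction > 0, fraction < 1)
  v <- kernel$values
  mx <- suppressWarnings(max(v, na.rm = TRUE))
  cell_km2 <- (kernel$cell_size / 1000)^2
  if (!is.finite(mx) || mx <= 0) {
    return(structure(list(
      labels = raster_grid(matrix(0, nrow(v), ncol(v)), xmin = kernel$xmin,
                           ymin = kernel$ymin, cell_size = kernel$cell_size,
                           crs = kernel$crs),
      patches = data.frame(id = integer(0), cells = integer(0),
                           area_km2 = numeric(0)),
      total_km2 = 0, cutoff = 0, fraction = fraction),
      class = "patch_set"))
  }
  cutoff <- fraction * mx
  mask <- !is.na(v) & v > cutoff
  lab <- cpp_label_components(mask, as.integer(connectivity))
  ids <- sort(unique(lab[lab > 0]))
  sizes <- tabulate(lab[lab > 0])
  patches <- data.frame(id = ids, cells = sizes[ids],
                        area_km2 = sizes[ids] * cell_km2)
  structure(list(
    labels = raster_grid(lab * 1.0, xmin = kernel$xmin, ymin = kernel$ymin,
                         cell_size = kernel$cell_size, crs = kernel$crs),
    patches = patches,
    total_km2 = sum(patches$area_km2),
    cutoff = cutoff, fraction = fraction),
    class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("patch_set: %d patches, %.2f km2 total (cutoff %.4g)\n",
              nrow(x$patches), x$total_km2, x$cutoff))
  invisible(x)
}

#' Corridor extent from a corridor-density surface
#'
#' Area (km2) of cells with density strictly above `positive_threshold`
#' (default 0: any positive corridor density counts).
#'
#' @param density a corridor-density [raster_grid()].
#' @param positive_threshold density cutoff.
#' @return extent in km2.
#' @export
corridor_extent <- function(density, positive_threshold = 0) {
  v <- density$values
  sum(v > positive_threshold, na.rm = TRUE) * (density$cell_size / 1000)^2
}

#' Rasterize protected-area polygons
#'
#' A cell is protected iff its center falls inside any polygon (consistent
#' with the center-based window convention used elsewhere).
#'
#' @param protected_areas list of closed polygon coordinate matrices.
#' @param template [raster_grid()] geometry.
#' @return logical matrix of protected cells.
#' @export
rasterize_protected <- function(protected_areas, template) {
  cc <- grid_cell_centers(template)
  inside <- rep(FALSE, nrow(cc))
  for (poly in protected_areas) {
    inside <- inside | mgcv::in.out(as.matrix(poly[, 1:2]),
                                    cbind(cc$x, cc$y))
  }
  matrix(inside, grid_nrow(template), grid_ncol(template))
}

#' Protected-area coverage of core habitats and corridors
#'
#' Intersects a core-habitat mask (a `patch_set`) or any positive-valued
#' surface with protected-area polygons and reports extent, protected
#' extent, and percent protected. With an empty protected-area set the
#' protected extent is 0 with a warning.
#'
#' @param x a `patch_set`, or a [raster_grid()] whose positive cells form
#'   the footprint (e.g. a corridor density surface).
#' @param protected_areas list of polygon matrices in the raster CRS.
#' @param scenario optional label for the report row.
#' @return one-row data.frame: `scenario`, `extent_km2`,
#'   `protected_km2`, `percent_protected` (unrounded), `percent_rounded`.
#' @export
protection_overlap <- function(x, protected_areas, scenario = NA) {
  if (inherits(x, "patch_set")) {
    mask <- x$labels$values > 0
    tmpl <- x$labels
  } else {
    mask <- !is.na(x$values) & x$values > 0
    tmpl <- x
  }
  cell_km2 <- (tmpl$cell_size / 1000)^2
  extent <- sum(mask) * cell_km2
  if (length(protected_areas) == 0) {
    warning("empty protected-area set: protected extent is 0")
    prot <- matrix(FALSE, nrow(mask), ncol(mask))
  } else {
    prot <- rasterize_protected(protected_areas, tmpl)
  }
  protected <- sum(mask & prot) * cell_km2
  pct <- if (extent > 0) 100 * protected / extent else 0
  data.frame(scenario = scenario, extent_km2 = extent,
             protected_km2 = protected, percent_protected = pct,
             percent_rounded = round(pct))
}

#' Protection report across dispersal scenarios
#'
#' One row per kernel dispersal threshold (core habitats) plus one row for
#' the corridor surface, in the layout of a protected-area accounting
#' table: extent, protected extent, percent protected.
#'
#' @param patch_sets named list of `patch_set`s (names = scenario labels,
#'   e.g. cost-unit thresholds).
#' @param corridor optional corridor-density [raster_grid()].
#' @param protected_areas list of polygon matrices.
#' @return data.frame, one row per scenario.
#' @export
protection_report <- function(patch_sets, corridor = NULL,
                              protected_areas = list()) {
  rows <- lapply(names(patch_sets), function(nm)
    protection_overlap(patch_sets[[nm]], protected_areas, scenario = nm))
  if (!is.null(corridor))
    rows <- c(rows, list(
      protection_overlap(corridor, protected_areas, scenario = "corridors")))
  do.call(rbind, rows)
}
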