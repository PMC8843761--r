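#' Single-band georeferenced raster grid
#'
#' A lightweight in-memory raster: a numeric matrix of cell values plus the
#' geometry needed to place it in a projected (planar, metric) coordinate
#' system. Row 1 is the north edge (GeoTIFF north-up convention); cell
#' values are located at cell centers. `NA` marks nodata.
#'
#' @param values numeric matrix of cell values (row 1 = north edge).
#' @param xmin,ymin coordinates (m) of the lower-left corner of the grid.
#' @param cell_size cell edge length in meters.
#' @param crs free-text tag for the projected CRS the coordinates live in.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, xmin = 0, ymin = 0, cell_size = 250,
                        crs = "local-projected-m") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (cell_size <= 0) stop("cell_size must be positive")
  structure(
    list(values = values, xmin = xmin, ymin = ymin,
         cell_size = cell_size, crs = crs),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("raster_grid: %d rows x %d cols @ %g m (crs: %s)\n",
              nrow(v), ncol(v), x$cell_size, x$crs))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g]\n",
              x$xmin, x$xmin + ncol(v) * x$cell_size,
              x$ymin, x$ymin + nrow(v) * x$cell_size))
  rng <- range(v, na.rm = TRUE)
  cat(sprintf("  values: [%g, %g], %d nodata cells\n",
              rng[1], rng[2], sum(is.na(v))))
  invisible(x)
}

grid_nrow <- function(g) nrow(g$values)
grid_ncol <- function(g) ncol(g$values)
grid_ymax <- function(g) g$ymin + grid_nrow(g) * g$cell_size

#' Cell-center coordinates of every cell
#'
#' @param g a [raster_grid()].
#' @return data.frame with columns `x`, `y`, `row`, `col`, `value`, in
#'   column-major matrix order.
#' @export
grid_cell_centers <- function(g) {
  nr <- grid_nrow(g); nc <- grid_ncol(g)
  row <- rep(seq_len(nr), times = nc)
  col <- rep(seq_len(nc), each = nr)
  data.frame(
    x = g$xmin + (col - 0.5) * g$cell_size,
    y = grid_ymax(g) - (row - 0.5) * g$cell_size,
    row = row, col = col,
    value = as.vector(g$values)
  )
}

#' Map point coordinates to raster row/col indices
#'
#' @param g a [raster_grid()].
#' @param x,y point coordinates (m).
#' @return data.frame with `row`, `col` (NA where outside the extent).
#' @export
grid_rowcol <- function(g, x, y) {
  col <- floor((x - g$xmin) / g$cell_size) + 1
  row <- floor((grid_ymax(g) - y) / g$cell_size) + 1
  bad <- col < 1 | col > grid_ncol(g) | row < 1 | row > grid_nrow(g)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Extract raster values at point locations
#'
#' @param g a [raster_grid()].
#' @param x,y point coordinates (m).
#' @return numeric vector of cell values (NA outside the extent or nodata).
#' @export
grid_extract <- function(g, x, y) {
  rc <- grid_rowcol(g, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc$row)
  out[ok] <- g$values[cbind(rc$row[ok], rc$col[ok])]
  out
}

#' Do two grids share the same geometry?
#' @param a,b [raster_grid()] objects.
#' @return logical.
#' @export
grid_aligned <- function(a, b) {
  isTRUE(all.equal(dim(a$values), dim(b$values))) &&
    isTRUE(all.equal(c(a$xmin, a$ymin, a$cell_size),
                     c(b$xmin, b$ymin, b$cell_size)))
}

stop_unless_aligned <- function(a, b, what = "rasters") {
  if (!grid_aligned(a, b)) stop(sprintf("%s are not aligned on the same grid", what))
  invisible(TRUE)
}

#' Write a raster to ESRI ASCII grid format
#'
#' Plain-text, georeferenced, readable by every GIS. Nodata is written as
#' -9999.
#'
#' @param g a [raster_grid()].
#' @param path output file path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(g, path) {
  v <- g$values
  v[is.na(v)] <- -9999
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", g$xmin),
    sprintf("yllcorner %.10g", g$ymin),
    sprintf("cellsize %.10g", g$cell_size),
    "NODATA_value -9999"
  ), con)
  utils::write.table(format(v, trim = TRUE, digits = 15, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid raster
#'
#' @param path file written by [write_ascii_grid()] (or any ESRI ASCII grid).
#' @param crs CRS tag to attach.
#' @return a [raster_grid()].
#' @export
read_ascii_grid <- function(path, crs = "local-projected-m") {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1))
  vals <- as.numeric(vapply(kv, `[`, "", 2))
  names(vals) <- keys
  nc <- as.integer(vals[["ncols"]]); nr <- as.integer(vals[["nrows"]])
  body <- scan(path, skip = 6, quiet = TRUE)
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == vals[["nodata_value"]]] <- NA_real_
  raster_grid(m, xmin = vals[["xllcorner"]], ymin = vals[["yllcorner"]],
              cell_size = vals[["cellsize"]], crs = crs)
}

# Evaluate code under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
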