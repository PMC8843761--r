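#' Transform habitat suitability to landscape resistance
#'
#' Movement resistance is assumed to decay exponentially with habitat
#' suitability: the raw transform is `raw = base^(-HS)` (base 1000 by
#' default), and the raw range `[base^-1, 1]` is then mapped linearly onto
#' `[1, 100]`, so resistance is exactly 1 where HS = 1 and exactly 100
#' where HS = 0. The transform is strictly decreasing and convex in HS:
#' most of the suitability range maps to low resistance, and only very
#' unsuitable cells receive high resistance.
#'
#' @param hs suitability [raster_grid()] (or numeric vector) with values
#'   in \[0, 1\]; nodata propagates.
#' @param base exponential base (default 1000).
#' @return resistance [raster_grid()] (or numeric vector) in \[1, 100\].
#' @export
suitability_to_resistance <- function(hs, base = 1000) {
  v <- if (inherits(hs, "raster_grid")) hs$values else hs
  ok <- !is.na(v)
  if (any(v[ok] < 0 | v[ok] > 1))
    stop("habitat suitability must lie in [0, 1]")
  raw <- base^(-v)
  lo <- base^(-1)
  r <- 1 + 99 * (raw - lo) / (1 - lo)
  if (!inherits(hs, "raster_grid")) return(r)
  out <- raster_grid(r, xmin = hs$xmin, ymin = hs$ymin,
                     cell_size = hs$cell_size, crs = hs$crs)
  attr(out, "provenance") <- list(
    source = "habitat suitability", base = base,
    hs_mean = mean(v[ok]), n_valid = sum(ok))
  out
}
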