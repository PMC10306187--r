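#' In-memory raster stack
#'
#' A lightweight container for a stack of co-registered 2-D grids sharing one
#' geotransform, with one timestamp per layer. Layers are matrices with rows
#' running north to south (decreasing latitude) and columns west to east
#' (increasing longitude), the convention of gridded earth-observation
#' products. Coordinates are WGS84 degrees; lon/lat of a cell refer to its
#' center.
#'
#' @param layers list of numeric matrices, all with identical dimensions.
#' @param extent numeric vector `c(xmin, xmax, ymin, ymax)` in degrees; the
#'   outer edges of the grid, not cell centers.
#' @param dates vector of `Date` (or coercible), one per layer, strictly
#'   increasing.
#' @param crs coordinate reference system label; only `"WGS84"` is handled.
#' @return An object of class `raster_stack`.
#' @export
raster_stack <- function(layers, extent, dates, crs = "WGS84") {
  if (!is.list(layers) || length(layers) == 0L)
    stop("`layers` must be a non-empty list of matrices")
  dm <- dim(layers[[1]])
  for (l in layers) {
    if (!is.matrix(l) || !identical(dim(l), dm))
      stop("all layers must be matrices sharing one dimension")
  }
  if (length(extent) != 4L || extent[1] >= extent[2] || extent[3] >= extent[4])
    stop("`extent` must be c(xmin, xmax, ymin, ymax) with xmin < xmax, ymin < ymax")
  dates <- as.Date(dates)
  if (length(dates) != length(layers)) stop("one date per layer required")
  if (anyNA(dates)) stop("unparseable date in `dates`")
  if (is.unsorted(dates, strictly = TRUE)) stop("`dates` must be strictly increasing")
  structure(
    list(layers = layers, extent = as.numeric(extent), dates = dates,
         ncol = dm[2], nrow = dm[1], crs = crs),
    class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  cat(sprintf("raster_stack: %d layer(s), %d x %d cells, %s .. %s\n",
              length(x$layers), x$nrow, x$ncol,
              format(min(x$dates)), format(max(x$dates))))
  cat(sprintf("  extent: lon [%g, %g], lat [%g, %g] (%s)\n",
              x$extent[1], x$extent[2], x$extent[3], x$extent[4], x$crs))
  invisible(x)
}

#' Cell-center coordinates of a raster stack
#'
#' @param stack a [raster_stack()].
#' @return list with `lon` (length ncol, ascending) and `lat` (length nrow,
#'   descending, matching row order).
#' @export
cell_centers <- function(stack) {
  dx <- (stack$extent[2] - stack$extent[1]) / stack$ncol
  dy <- (stack$extent[4] - stack$extent[3]) / stack$nrow
  list(
    lon = stack$extent[1] + dx * (seq_len(stack$ncol) - 0.5),
    lat = stack$extent[4] - dy * (seq_len(stack$nrow) - 0.5))
}
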