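#' Convert a masked raster stack to a long observation table
#'
#' Flattens a stack of gridded values into the long format the models consume:
#' one row per (masked-in pixel, layer) combination carrying the pixel-center
#' longitude/latitude, the layer date and the cell value. Rows whose value is
#' missing are dropped; analyses use available composites only.
#'
#' @param stack a [raster_stack()].
#' @param mask logical (or 0/1) matrix with the stack's dimensions; `TRUE`
#'   cells are retained (e.g. a cropland mask).
#' @param value_name name for the value column (default `"gpp"`).
#' @return A tibble with columns `longitude`, `latitude`, `date` and the value
#'   column, sorted by (longitude, latitude, date) with strictly increasing
#'   dates within each pixel.
#' @export
build_long_table <- function(stack, mask, value_name = "gpp") {
  stopifnot(inherits(stack, "raster_stack"))
  mask <- as.matrix(mask)
  if (!identical(dim(mask), c(stack$nrow, stack$ncol)))
    stop("mask dimensions must equal the stack's layer dimensions")
  mask <- !is.na(mask) & (mask != 0)
  cc <- cell_centers(stack)
  idx <- which(mask)                       # column-major cell indices
  row_i <- ((idx - 1L) %% stack$nrow) + 1L
  col_i <- ((idx - 1L) %/% stack$nrow) + 1L
  nt <- length(stack$layers)
  lon <- rep(cc$lon[col_i], times = nt)
  lat <- rep(cc$lat[row_i], times = nt)
  date <- rep(stack$dates, each = length(idx))
  val <- unlist(lapply(stack$layers, function(l) l[idx]), use.names = FALSE)
  keep <- !is.na(val)
  if (!any(keep) && length(val) > 0L)
    warning("all masked values are missing; returning an empty table")
  out <- tibble::tibble(longitude = lon[keep], latitude = lat[keep],
                        date = date[keep])
  out[[value_name]] <- val[keep]
  # stable pixel key: coordinates rounded to 1e-6 degrees
  o <- order(round(out$longitude, 6), round(out$latitude, 6), out$date)
  out[o, ]
}

#' Attach calendar columns derived from the date
#'
#' Splits `date` into integer `year`, `month` and `day` columns. Dates must
#' already be valid `Date`s or ISO `yyyy-mm-dd` strings; an unparseable entry
#' is an error naming the offending row.
#'
#' @param table a long table with a `date` column.
#' @return the table with `year`, `month`, `day` appended.
#' @export
add_calendar_columns <- function(table) {
  if (!"date" %in% names(table)) stop("`table` must have a `date` column")
  d <- as.Date(as.character(table$date), format = "%Y-%m-%d")
  bad <- which(is.na(d))
  if (length(bad))
    stop(sprintf("unparseable date in row %d: '%s'", bad[1],
                 as.character(table$date[bad[1]])))
  table$date <- d
  table$year <- as.integer(format(d, "%Y"))
  table$month <- as.integer(format(d, "%m"))
  table$day <- as.integer(format(d, "%d"))
  table
}

#' Label observations as pre or post a disruption date
#'
#' Adds a two-level factor `war` marking each row as before or after the
#' event cutoff. The cutoff date itself is labelled `post` (inclusive
#' boundary).
#'
#' @param table a long table with a `date` column.
#' @param cutoff the event date; default 2022-02-24.
#' @return the table with a `war` factor (`pre` reference level, `post`).
#' @export
label_event <- function(table, cutoff = as.Date("2022-02-24")) {
  if (!"date" %in% names(table)) stop("`table` must have a `date` column")
  cutoff <- as.Date(cutoff)
  table$war <- factor(ifelse(as.Date(table$date) >= cutoff, "post", "pre"),
                      levels = c("pre", "post"))
  table
}

#' Read / write a long observation table as CSV
#'
#' Plain-text round trip for the long format (columns exactly `longitude`,
#' `latitude`, `date`, value, and any calendar/event columns present). Values
#' survive the round trip bit-exactly for finite doubles.
#'
#' @param table a long table.
#' @param path file path.
#' @return `read_long_table()` returns a tibble; `write_long_table()` returns
#'   `path` invisibly.
#' @export
write_long_table <- function(table, path) {
  tab <- table
  num <- vapply(tab, is.double, logical(1))
  # full precision so the round trip is exact
  tab[num] <- lapply(tab[num], function(x) sprintf("%.17g", x))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_long_table
#' @export
read_long_table <- function(path) {
  # base read.csv: strtod parsing is correctly rounded, so %.17g survives
  tab <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if ("date" %in% names(tab)) tab$date <- as.Date(tab$date)
  if ("war" %in% names(tab)) tab$war <- factor(tab$war, levels = c("pre", "post"))
  tab
}

# pixel key used for AR(1) grouping: coordinates rounded to 1e-6 degrees
pixel_key <- function(table) {
  paste(sprintf("%.6f", table$longitude), sprintf("%.6f", table$latitude))
}
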