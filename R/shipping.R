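#' @title Shipping route-density extraction around ports
#' @description
#' Zonal extraction of monthly cargo route-density rasters: the unweighted
#' mean of cells whose centers fall within a great-circle radius of a port
#' (default 20 km), assembled into per-port monthly series, within-year
#' cumulative sums, and year-on-year percent change of the cumulative
#' activity.
#' @name shipping
NULL

#' Port buffer zones
#'
#' @param name port names.
#' @param lon,lat coordinates in degrees.
#' @param radius buffer radius in meters (default 20,000).
#' @return a `PortZone` tibble.
#' @export
port_zone <- function(name, lon, lat, radius = 20000) {
  if (any(radius <= 0)) stop("radius must be positive")
  tibble::tibble(name = as.character(name), lon = as.numeric(lon),
                 lat = as.numeric(lat), radius = as.numeric(radius))
}

#' Black Sea port zones used for the 2021/2022 comparison
#'
#' Odesa (30.74E, 46.50N), Mariupol (38.14E, 46.97N) and Constanta
#' (28.74E, 44.07N), each with the standard 20 km extraction radius.
#'
#' @param radius buffer radius in meters (default 20,000).
#' @return a `PortZone` tibble.
#' @export
black_sea_ports <- function(radius = 20000) {
  port_zone(c("Odesa", "Mariupol", "Constanta"),
            lon = c(30.74, 38.14, 28.74),
            lat = c(46.50, 46.97, 44.07),
            radius = radius)
}

#' Mean raster value within a great-circle radius of a point
#'
#' Unweighted mean over cells whose centers lie within `radius` meters
#' (haversine distance) of the zone point; missing cells are excluded. Zero
#' intersecting cells is an error.
#'
#' @param stack a [raster_stack()].
#' @param zone one-row `PortZone` (or list with `name`, `lon`, `lat`,
#'   `radius`).
#' @param layer layer index (default 1).
#' @return the mean density (scalar).
#' @export
buffer_mean <- function(stack, zone, layer = 1) {
  stopifnot(inherits(stack, "raster_stack"))
  cc <- cell_centers(stack)
  lon_m <- matrix(rep(cc$lon, each = stack$nrow), stack$nrow, stack$ncol)
  lat_m <- matrix(rep(cc$lat, times = stack$ncol), stack$nrow, stack$ncol)
  d_km <- haversine_km(lon_m, lat_m, zone$lon, zone$lat)
  sel <- d_km <= zone$radius / 1000
  if (!any(sel))
    stop(sprintf("zone '%s' has no raster cells within %.0f m", zone$name,
                 zone$radius))
  vals <- stack$layers[[layer]][sel]
  if (all(is.na(vals)))
    stop(sprintf("zone '%s': all cells within the buffer are missing", zone$name))
  mean(vals, na.rm = TRUE)
}

#' Monthly mean route density per port
#'
#' Extracts [buffer_mean()] for every (zone, layer) combination and attaches
#' calendar columns. A zone outside the raster extent is an error naming the
#' zone. Rows are ordered by (port, date).
#'
#' @param stack a [raster_stack()] of monthly layers.
#' @param zones a `PortZone` tibble (see [port_zone()]).
#' @return a `ShippingSeries` tibble: `port`, `date`, `year`, `month`,
#'   `density`.
#' @export
monthly_series <- function(stack, zones) {
  ex <- stack$extent
  for (i in seq_len(nrow(zones))) {
    if (zones$lon[i] < ex[1] || zones$lon[i] > ex[2] ||
        zones$lat[i] < ex[3] || zones$lat[i] > ex[4])
      stop(sprintf("zone '%s' lies outside the raster extent", zones$name[i]))
  }
  rows <- expand.grid(zi = seq_len(nrow(zones)), li = seq_along(stack$layers))
  dens <- mapply(function(zi, li) buffer_mean(stack, zones[zi, ], li),
                 rows$zi, rows$li)
  out <- tibble::tibble(
    port = zones$name[rows$zi],
    date = stack$dates[rows$li],
    density = as.numeric(dens))
  out$year <- as.integer(format(out$date, "%Y"))
  out$month <- as.integer(format(out$date, "%m"))
  dplyr::arrange(out, .data$port, .data$date)
}

#' Within-year cumulative route density
#'
#' Adds the cumulative sum of monthly mean density within each (port, year),
#' restarting every January. Non-decreasing whenever densities are
#' non-negative.
#'
#' @param series a `ShippingSeries` tibble from [monthly_series()] (or any
#'   tibble with `port`, `date`, `year`, `density`).
#' @return the series with a `cumulative` column, ordered by (port, date).
#' @export
cumulative_by_year <- function(series) {
  series |>
    dplyr::arrange(.data$port, .data$date) |>
    dplyr::group_by(.data$port, .data$year) |>
    dplyr::mutate(cumulative = cumsum(.data$density)) |>
    dplyr::ungroup()
}

#' Year-on-year percent change of cumulative shipping activity
#'
#' `100 * (cum_b[compare_month] - cum_a[compare_month]) / cum_a[reference_month]`
#' per port; negative values are declines. By default both months are the
#' last month observed in *both* years, so the same-length year portions are
#' compared.
#'
#' @param series a cumulative series from [cumulative_by_year()].
#' @param year_a baseline year.
#' @param year_b comparison year.
#' @param compare_month,reference_month month numbers (1-12); default: the
#'   last month common to both years.
#' @return tibble with `port`, `percent` (and the months used).
#' @export
percent_change <- function(series, year_a, year_b,
                           compare_month = NULL, reference_month = NULL) {
  if (!"cumulative" %in% names(series))
    series <- cumulative_by_year(series)
  out <- lapply(unique(series$port), function(p) {
    sa <- series[series$port == p & series$year == year_a, ]
    sb <- series[series$port == p & series$year == year_b, ]
    if (nrow(sa) == 0 || nrow(sb) == 0)
      stop(sprintf("port '%s' missing data for year %d or %d", p, year_a, year_b))
    common <- intersect(sa$month, sb$month)
    cm <- if (is.null(compare_month)) max(common) else compare_month
    rm_ <- if (is.null(reference_month)) cm else reference_month
    ca <- sa$cumulative[match(cm, sa$month)]
    cb <- sb$cumulative[match(cm, sb$month)]
    ref <- sa$cumulative[match(rm_, sa$month)]
    if (anyNA(c(ca, cb, ref)))
      stop(sprintf("port '%s': month %d/%d not present in both years", p, cm, rm_))
    if (ref == 0) stop(sprintf("port '%s': zero reference cumulative value", p))
    tibble::tibble(port = p, percent = 100 * (cb - ca) / ref,
                   compare_month = cm, reference_month = rm_)
  })
  dplyr::bind_rows(out)
}
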