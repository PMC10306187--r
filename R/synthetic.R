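#' @title Synthetic data with known truth
#' @description
#' Generators that emulate the statistical structure the pipeline assumes:
#' a gridded GPP-like field built from a smooth spatial mean, an exactly
#' periodic 12-month seasonal curve, a linear inter-annual trend, an optional
#' space-by-season interaction, an additive post-cutoff step change, per-pixel
#' AR(1) noise and white observation noise; and monthly shipping route-density
#' rasters with corridor structure, optional per-year scaling and blackout
#' windows. Every generator takes an explicit seed and returns the truth it
#' used, so recovery can be tested end to end.
#' @name synthetic_data
NULL

#' Simulation configuration for the GPP-like field
#'
#' Defaults describe the desk-scale scene used throughout the tests: a
#' 16 x 16 pixel grid observed twice a month for three years (18,432 rows),
#' seasonal amplitude 1.5 gC/m2 peaking in June, two spatial bumps on a base
#' level of 2 gC/m2, a -0.247 gC/m2 step at the 2022-02-24 cutoff, AR(1)
#' noise (rho 0.3, marginal sd 0.35) plus white noise sd 0.5.
#'
#' @param nx,ny grid size in pixels.
#' @param lon_range,lat_range extent in degrees.
#' @param years integer vector of years.
#' @param epochs_per_month observations per pixel per month.
#' @param seasonal_amp,seasonal_phase cosine seasonal amplitude (gC/m2) and
#'   peak month.
#' @param trend_slope linear inter-annual trend (gC/m2 per year).
#' @param base_level spatial mean base level (gC/m2).
#' @param bumps data frame of Gaussian bumps: `lon`, `lat`, `height`,
#'   `width` (degrees).
#' @param interaction_amp amplitude of the seasonal-by-longitude interaction.
#' @param delta additive step change applied from `cutoff` on (gC/m2).
#' @param cutoff step-change date.
#' @param post_phase_shift months by which the seasonal curve is shifted
#'   after the cutoff (0 = same seasonality pre/post).
#' @param rho,ar_sd AR(1) correlation and marginal sd of the AR(1) noise.
#' @param sigma white observation noise sd.
#' @param seed integer seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(nx = 16, ny = 16,
                       lon_range = c(30, 33), lat_range = c(46, 49),
                       years = 2020:2022, epochs_per_month = 2,
                       seasonal_amp = 1.5, seasonal_phase = 6,
                       trend_slope = 0.05, base_level = 2,
                       bumps = data.frame(lon = c(30.8, 32.3),
                                          lat = c(46.7, 48.2),
                                          height = c(1, 0.6),
                                          width = c(0.8, 0.6)),
                       interaction_amp = 0.15,
                       delta = -0.247, cutoff = as.Date("2022-02-24"),
                       post_phase_shift = 0,
                       rho = 0.3, ar_sd = 0.35, sigma = 0.5,
                       seed = 20230628) {
  stopifnot(sigma >= 0, ar_sd >= 0, abs(rho) < 1,
            lon_range[1] < lon_range[2], lat_range[1] < lat_range[2])
  structure(as.list(environment()), class = "sim_config")
}

# reduced modulo the period first, so value(m) == value(m + 12) exactly
seasonal_curve <- function(m, amp, phase) {
  amp * cos(2 * pi * ((m - phase) %% 12) / 12)
}

#' Simulate a GPP-like long table with known truth
#'
#' Value = spatial(s) + seasonal(month) + trend(year) + interaction +
#' `delta` for dates on/after the cutoff + AR(1) noise + white noise. The
#' seasonal curve is exactly periodic in the integer month. Returns both the
#' long table (with calendar columns and the `war` factor attached) and the
#' truth components as used.
#'
#' @param config a [sim_config()].
#' @return list with `table` (a long tibble sorted by pixel then date) and
#'   `truth` (spatial field per pixel, seasonal curve on months 1-12, annual
#'   trend values, `delta`, `rho`, the config).
#' @export
simulate_gpp <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  set.seed(cf$seed)
  dx <- diff(cf$lon_range) / cf$nx
  dy <- diff(cf$lat_range) / cf$ny
  lon <- cf$lon_range[1] + dx * (seq_len(cf$nx) - 0.5)
  lat <- cf$lat_range[1] + dy * (seq_len(cf$ny) - 0.5)
  px <- expand.grid(longitude = lon, latitude = lat)
  n_px <- nrow(px)
  spatial <- rep(cf$base_level, n_px)
  if (!is.null(cf$bumps) && nrow(cf$bumps) > 0) {
    for (b in seq_len(nrow(cf$bumps))) {
      spatial <- spatial + cf$bumps$height[b] *
        exp(-((px$longitude - cf$bumps$lon[b])^2 +
                (px$latitude - cf$bumps$lat[b])^2) / (2 * cf$bumps$width[b]^2))
    }
  }
  E <- cf$epochs_per_month
  days <- floor((seq_len(E) - 0.5) * 28 / E) + 1L
  cal <- expand.grid(day = days, month = 1:12, year = cf$years)
  cal <- cal[order(cal$year, cal$month, cal$day), ]
  dates <- as.Date(sprintf("%d-%02d-%02d", cal$year, cal$month, cal$day))
  nt <- length(dates)
  zlon <- (px$longitude - mean(cf$lon_range)) / (diff(cf$lon_range) / 2)
  seas <- seasonal_curve(cal$month, cf$seasonal_amp, cf$seasonal_phase)
  seas_post <- seasonal_curve(cal$month + cf$post_phase_shift,
                              cf$seasonal_amp, cf$seasonal_phase)
  trend <- cf$trend_slope * (cal$year - mean(cf$years))
  post <- as.numeric(dates >= cf$cutoff)
  # mean surface: pixel-major blocks (each pixel's full time series contiguous)
  mu <- matrix(0, nt, n_px)
  for (j in seq_len(n_px)) {
    sj <- seas * (1 - post) + seas_post * post
    mu[, j] <- spatial[j] + sj + trend +
      cf$interaction_amp * seasonal_curve(cal$month, 1, cf$seasonal_phase) * zlon[j] +
      cf$delta * post
  }
  noise <- matrix(0, nt, n_px)
  if (cf$ar_sd > 0) {
    innov_sd <- cf$ar_sd * sqrt(1 - cf$rho^2)
    e <- matrix(stats::rnorm(nt * n_px, 0, innov_sd), nt, n_px)
    e[1, ] <- stats::rnorm(n_px, 0, cf$ar_sd)     # stationary start
    for (t in 2:nt) e[t, ] <- cf$rho * e[t - 1, ] + e[t, ]
    noise <- noise + e
  }
  if (cf$sigma > 0)
    noise <- noise + matrix(stats::rnorm(nt * n_px, 0, cf$sigma), nt, n_px)
  tab <- tibble::tibble(
    longitude = rep(px$longitude, each = nt),
    latitude = rep(px$latitude, each = nt),
    date = rep(dates, times = n_px),
    gpp = as.numeric(mu + noise))
  tab <- add_calendar_columns(tab)
  tab <- label_event(tab, cf$cutoff)
  tab <- sort_long_table(tab)
  truth <- list(
    pixels = tibble::tibble(longitude = px$longitude, latitude = px$latitude,
                            spatial = spatial),
    seasonal = tibble::tibble(month = 1:12,
                              value = seasonal_curve(1:12, cf$seasonal_amp,
                                                     cf$seasonal_phase)),
    trend = tibble::tibble(year = cf$years,
                           value = cf$trend_slope * (cf$years - mean(cf$years))),
    delta = cf$delta, rho = cf$rho, config = cf)
  list(table = tab, truth = truth)
}

#' Simulate monthly shipping route-density rasters
#'
#' Builds a stack of monthly density grids with Gaussian-ridge corridors
#' running from each port to a common offshore hub, a hotspot at each port, a
#' fixed month-of-year activity profile (so identical months in different
#' years differ only by `year_scale`), optional per-port-per-year scaling,
#' and optional blackout windows during which a port's entire contribution is
#' zeroed. Densities are non-negative everywhere.
#'
#' @param months a `Date` vector of month starts (one layer each).
#' @param ports data frame with `name`, `lon`, `lat`.
#' @param extent raster extent `c(xmin, xmax, ymin, ymax)`.
#' @param nx,ny grid size.
#' @param hub lon/lat of the offshore hub the corridors converge on.
#' @param corridor_width_km Gaussian ridge width.
#' @param corridor_height ridge peak density (routes/km2/month).
#' @param profile_sd lognormal sd of the month-of-year activity profile.
#' @param year_scale optional data frame `name`, `year`, `scale` multiplying
#'   a port's contribution in that year.
#' @param blackout optional data frame `name`, `from`, `to` (Dates): months
#'   whose start falls in [from, to] contribute zero for that port.
#' @param seed integer seed (drives the monthly profile only).
#' @return a [raster_stack()] of monthly densities.
#' @export
simulate_shipping <- function(months, ports,
                              extent = c(27, 40, 43, 48), nx = 130, ny = 60,
                              hub = c(33.5, 44.3),
                              corridor_width_km = 25, corridor_height = 5,
                              profile_sd = 0.2, year_scale = NULL,
                              blackout = NULL, seed = 20230628) {
  months <- sort(as.Date(months))
  set.seed(seed)
  profile <- exp(stats::rnorm(12, 0, profile_sd))   # month-of-year multipliers
  dx <- (extent[2] - extent[1]) / nx
  dy <- (extent[4] - extent[3]) / ny
  lon <- extent[1] + dx * (seq_len(nx) - 0.5)
  lat <- extent[4] - dy * (seq_len(ny) - 0.5)
  cell_lon <- matrix(rep(lon, each = ny), ny, nx)
  cell_lat <- matrix(rep(lat, times = nx), ny, nx)
  # local-plane km distance from each cell to the segment port-hub
  seg_dist_km <- function(plon, plat) {
    latref <- mean(extent[3:4]) * pi / 180
    kx <- 111.32 * cos(latref); ky <- 110.57
    ax <- (plon - cell_lon) * kx; ay <- (plat - cell_lat) * ky
    bx <- (hub[1] - cell_lon) * kx; by <- (hub[2] - cell_lat) * ky
    vx <- bx - ax; vy <- by - ay
    tt <- pmin(1, pmax(0, -(ax * vx + ay * vy) / (vx^2 + vy^2)))
    sqrt((ax + tt * vx)^2 + (ay + tt * vy)^2)
  }
  port_fields <- lapply(seq_len(nrow(ports)), function(i) {
    d <- seg_dist_km(ports$lon[i], ports$lat[i])
    dp <- haversine_km(cell_lon, cell_lat, ports$lon[i], ports$lat[i])
    corridor_height * exp(-d^2 / (2 * corridor_width_km^2)) +
      2 * corridor_height * exp(-dp^2 / (2 * (corridor_width_km / 2)^2))
  })
  layers <- lapply(months, function(mo) {
    m <- as.integer(format(mo, "%m")); yr <- as.integer(format(mo, "%Y"))
    L <- matrix(0, ny, nx)
    for (i in seq_len(nrow(ports))) {
      sc <- 1
      if (!is.null(year_scale)) {
        hit <- year_scale$name == ports$name[i] & year_scale$year == yr
        if (any(hit)) sc <- year_scale$scale[which(hit)[1]]
      }
      if (!is.null(blackout)) {
        hit <- blackout$name == ports$name[i] &
          mo >= as.Date(blackout$from) & mo <= as.Date(blackout$to)
        if (any(hit)) sc <- 0
      }
      L <- L + sc * profile[m] * port_fields[[i]]
    }
    L
  })
  raster_stack(layers, extent, months)
}
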