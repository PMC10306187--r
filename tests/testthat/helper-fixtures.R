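# Shared fixtures: small-scene simulation configs and lazily cached fits so
# expensive model fits are reused across tests within a file run.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fixture_cache))
    assign(key, force(expr), envir = fixture_cache)
  get(key, envir = fixture_cache)
}

# small event-model scene: 36 pixels x 2 years x 1 epoch/month = 864 rows
small_event_config <- function(seed = 101, delta = -0.247, ...) {
  sim_config(nx = 6, ny = 6, years = 2021:2022, epochs_per_month = 1,
             trend_slope = 0, delta = delta, rho = 0.2, ar_sd = 0.3,
             sigma = 0.4, seed = seed, ...)
}

small_model_config <- function(...) {
  model_config(space_k = 15, space_rank_tensor = 8, ...)
}

small_event_fit <- function() {
  cached("small_event_fit", {
    sim <- simulate_gpp(small_event_config())
    fit_event_model(sim$table, small_model_config())
  })
}

small_event_sim <- function() {
  cached("small_event_sim", simulate_gpp(small_event_config()))
}

# small trend-model scene: 11 years for validation-style checks
trend_sim_config <- function(seed = 42, trend_slope = 0.08, sigma = 0.5, ...) {
  sim_config(nx = 8, ny = 8, years = 2010:2020, epochs_per_month = 1,
             trend_slope = trend_slope, delta = 0, rho = 0.3, sigma = sigma,
             seed = seed, ...)
}

small_trend_fit <- function() {
  cached("small_trend_fit", {
    sim <- simulate_gpp(trend_sim_config())
    fit_trend_model(sim$table, model_config(space_k = 30))
  })
}

small_trend_sim <- function() {
  cached("small_trend_sim", simulate_gpp(trend_sim_config()))
}

# AR(1) residual table: n_px pixels x n_t epochs with pure AR(1) noise
ar1_residual_table <- function(n_px = 200, n_t = 50, rho = 0.6, seed = 1) {
  set.seed(seed)
  dates <- seq(as.Date("2020-01-01"), by = 7, length.out = n_t)
  r <- matrix(rnorm(n_t * n_px, 0, sqrt(1 - rho^2)), n_t, n_px)
  r[1, ] <- rnorm(n_px)
  for (t in 2:n_t) r[t, ] <- rho * r[t - 1, ] + r[t, ]
  tab <- tibble::tibble(
    longitude = rep(seq_len(n_px) * 0.01 + 30, each = n_t),
    latitude = 47,
    date = rep(dates, times = n_px))
  list(table = tab, residuals = as.numeric(r))
}

# tiny raster stack for data-model tests
toy_stack <- function(nl = 2, nr = 3, nc = 3, extent = c(30, 33, 46, 49),
                      fill = NULL, seed = 5) {
  set.seed(seed)
  layers <- lapply(seq_len(nl), function(i) {
    if (is.null(fill)) matrix(rnorm(nr * nc), nr, nc)
    else matrix(fill, nr, nc)
  })
  raster_stack(layers, extent,
               seq(as.Date("2022-01-01"), by = "month", length.out = nl))
}
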