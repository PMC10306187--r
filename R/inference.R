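#' @title Effect extraction, step-change testing and uncertainty mapping
#' @description
#' Post-fit inference: summed effect curves over a covariate grid (intercept
#' plus the selected smooth, other covariates held at reference values),
#' prediction surfaces over space with standard errors, the Wald test on the
#' pre/post step-change coefficient, and the 3 x 3 bivariate tercile
#' classification used to map estimates together with their uncertainty.
#' @name inference
NULL

default_conditioning <- function(fit, level = NULL) {
  nd <- tibble::tibble(year = fit$conditioning$year,
                       month = fit$conditioning$month,
                       longitude = fit$conditioning$longitude,
                       latitude = fit$conditioning$latitude)
  nd$war <- if (is.null(level)) "pre" else level
  nd
}

#' Summed effect of a model term over a covariate grid
#'
#' Evaluates intercept + the selected smooth term(s) over a grid of the
#' term's covariate, holding every other covariate at its reference value
#' (training medians; the event factor at the requested level, whose
#' parametric coefficient is then included). Standard errors come from the
#' posterior covariance of the involved coefficients via the delta method on
#' the linear predictor. Grid values outside the training range trigger a
#' warning and are extrapolated linearly (splines) or periodically (cyclic).
#'
#' @param fit a `cropgam_fit`.
#' @param term `"year"`, `"month"` or `"space"` (matched against smooth
#'   labels), or an exact label substring.
#' @param grid covariate values to evaluate at; defaults to a fine grid over
#'   the training range (the observed years for `"year"`).
#' @param level optional event-factor level (`"pre"` or `"post"`) selecting
#'   the by-level smooth copies and including the factor coefficient when
#'   `"post"`.
#' @param conditioning optional one-row data frame overriding the reference
#'   covariate values.
#' @return an `EffectCurve` tibble: grid value, `estimate`, `se`, `term`,
#'   `level`.
#' @export
effect_curve <- function(fit, term = c("year", "month", "space"),
                         grid = NULL, level = NULL, conditioning = NULL) {
  term <- if (length(term) > 1) match.arg(term) else term
  labels <- names(fit$design_terms)
  sel_lab <- switch(term,
    year = grep("s(year)", labels, fixed = TRUE, value = TRUE),
    month = grep("s(month", labels, fixed = TRUE, value = TRUE),
    space = grep("gp)", labels, fixed = TRUE, value = TRUE),
    grep(term, labels, fixed = TRUE, value = TRUE))
  if (!is.null(level))
    sel_lab <- grep(paste0("war", level), sel_lab, value = TRUE, fixed = TRUE)
  else if (any(grepl(":war", labels)))
    stop("fit has by-factor smooths; supply `level` ('pre' or 'post')")
  if (length(sel_lab) == 0 && length(labels) > 0) {
    if (term %in% c("year", "month", "space"))
      stop(sprintf("no '%s' term in this fit", term))
  }
  gvar <- switch(term, year = "year", month = "month", term)
  if (is.null(grid)) {
    grid <- switch(term,
      year = fit$years,
      month = seq(1, 12, by = 0.25),
      stop("supply `grid` for this term"))
  }
  rng <- fit$train_range[[gvar]]
  if (!is.null(rng) && gvar != "month" &&
      (min(grid) < rng[1] || max(grid) > rng[2]))
    warning(sprintf("grid extends beyond the training range of %s; extrapolating linearly", gvar))
  nd <- default_conditioning(fit, level)[rep(1, length(grid)), ]
  nd[[gvar]] <- grid
  # intercept + factor dummy (0 for pre, 1 for post, from newdata) + the
  # selected smooth columns; every other term is zeroed
  X <- predict_design(fit, nd, terms = if (length(sel_lab)) sel_lab else character())
  pr <- predict_with_se(fit, X)
  out <- tibble::tibble(grid = grid, estimate = pr$estimate, se = pr$se,
                        term = paste(sel_lab, collapse = "+"),
                        level = if (is.null(level)) NA_character_ else level)
  names(out)[1] <- gvar
  out
}

#' Prediction surface over space with uncertainty classes
#'
#' Evaluates the full linear predictor on a longitude/latitude grid with the
#' temporal covariates at their reference values and the event factor at the
#' requested level. Grid nodes outside the convex hull of the training pixels
#' are flagged (`in_hull = FALSE`); estimates there are extrapolation.
#'
#' @param fit a `cropgam_fit`.
#' @param lon_grid,lat_grid grid node coordinates; default 40 steps across
#'   the training extent.
#' @param level event-factor level (default `"pre"`; ignored if the fit has
#'   no factor).
#' @param classify attach bivariate tercile classes and hex colors
#'   (default `TRUE`).
#' @return a `SpatialPrediction` tibble: `longitude`, `latitude`,
#'   `estimate`, `se`, `in_hull`, `level`, and (classified) `class`, `hex`.
#' @export
predict_surface <- function(fit, lon_grid = NULL, lat_grid = NULL,
                            level = "pre", classify = TRUE) {
  if (is.null(lon_grid))
    lon_grid <- seq(fit$train_range$longitude[1], fit$train_range$longitude[2],
                    length.out = 40)
  if (is.null(lat_grid))
    lat_grid <- seq(fit$train_range$latitude[1], fit$train_range$latitude[2],
                    length.out = 40)
  gr <- expand.grid(longitude = lon_grid, latitude = lat_grid)
  nd <- default_conditioning(fit, if (is.null(fit$factor_col)) NULL else level)
  nd <- nd[rep(1, nrow(gr)), ]
  nd$longitude <- gr$longitude
  nd$latitude <- gr$latitude
  X <- predict_design(fit, nd)
  pr <- predict_with_se(fit, X)
  hull <- fit$pixel_hull
  inh <- pracma::inpolygon(gr$longitude, gr$latitude, hull[, 1], hull[, 2])
  out <- tibble::tibble(longitude = gr$longitude, latitude = gr$latitude,
                        estimate = pr$estimate, se = pr$se,
                        in_hull = as.logical(inh),
                        level = if (is.null(fit$factor_col)) NA_character_ else level)
  if (classify) {
    bt <- bivariate_terciles(out$estimate, out$se)
    out$class <- bt$class
    out$hex <- bt$hex
  }
  out
}

#' Wald test of the pre/post step change
#'
#' The event-factor coefficient divided by its standard error (from the
#' sampling covariance of the penalized estimator), referred to a t
#' distribution on the residual degrees of freedom (normal approximation
#' beyond 1e4 dof); two-sided p.
#'
#' @param fit a `cropgam_fit` from [fit_event_model()].
#' @return list with `estimate`, `se`, `t`, `df`, `p`.
#' @export
event_effect_test <- function(fit) {
  if (is.null(fit$factor_col))
    stop("fit has no event factor; use fit_event_model()")
  j <- fit$factor_col
  est <- unname(fit$coefficients[j])
  se <- sqrt(fit$Ve[j, j])
  tval <- est / se
  df <- fit$df_residual
  p <- if (df > 1e4) 2 * stats::pnorm(-abs(tval)) else 2 * stats::pt(-abs(tval), df)
  list(estimate = est, se = se, t = tval, df = df, p = p)
}

#' Bivariate tercile classification for uncertainty maps
#'
#' Classifies each (estimate, standard error) pair into one of 9 classes by
#' crossing sample terciles of the estimates with sample terciles of the
#' standard errors: `class = 3 * (se tercile - 1) + estimate tercile`. Ties
#' fall to the lower class. A deterministic 3 x 3 palette (estimate terciles
#' in deepening greens, uncertainty terciles blending toward purple) supplies
#' one hex color per class.
#'
#' @param estimates,ses numeric vectors of equal length.
#' @param palette optional 9 hex colors (class order 1..9) overriding the
#'   default.
#' @return list with `class` (integer 1-9 per pair), `hex` (per pair),
#'   `palette` (the 9 colors), `breaks` (the tercile cut points used).
#' @export
bivariate_terciles <- function(estimates, ses, palette = NULL) {
  if (length(estimates) != length(ses)) stop("lengths differ")
  terc_idx <- function(x) {
    q <- stats::quantile(x, c(1/3, 2/3), type = 7, names = FALSE)
    ifelse(x <= q[1], 1L, ifelse(x <= q[2], 2L, 3L))
  }
  ei <- terc_idx(estimates)
  si <- terc_idx(ses)
  cls <- 3L * (si - 1L) + ei
  if (is.null(palette)) {
    greens <- c("#e5f5e0", "#a1d99b", "#31a354")
    purple <- grDevices::col2rgb("#762a83")
    mix <- function(hex, w) {
      g <- grDevices::col2rgb(hex)
      v <- round((1 - w) * g + w * purple)
      grDevices::rgb(v[1], v[2], v[3], maxColorValue = 255)
    }
    palette <- as.character(sapply(c(0, 0.35, 0.7), function(w)
      vapply(greens, mix, "", w = w)))
  }
  if (length(palette) != 9) stop("palette must supply 9 colors")
  list(class = cls, hex = palette[cls], palette = palette,
       breaks = list(estimate = stats::quantile(estimates, c(1/3, 2/3), names = FALSE),
                     se = stats::quantile(ses, c(1/3, 2/3), names = FALSE)))
}
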