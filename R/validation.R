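#' @title Validation against annual production series
#' @description
#' The model's inter-annual effect series is compared against an external
#' annual crop-production series (FAOSTAT-style tonnage): both series are
#' checked for normality with a Shapiro-Wilk test, then related with a
#' one-sided Pearson correlation test for a positive association.
#' @name validation
NULL

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around [stats::shapiro.test()] returning the statistic and
#' p-value, with the input checks the validation workflow needs (3 to 5000
#' observations, non-constant).
#'
#' @param x numeric vector.
#' @return list with `W` and `p`.
#' @export
shapiro_wilk <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3 || length(x) > 5000)
    stop("shapiro_wilk needs 3 <= n <= 5000")
  if (stats::sd(x) == 0) stop("constant vector: normality test undefined")
  st <- stats::shapiro.test(x)
  list(W = unname(st$statistic), p = st$p.value)
}

#' One-sided Pearson correlation test
#'
#' Sample correlation `r`, `t = r sqrt(df / (1 - r^2))` on `df = n - 2`
#' degrees of freedom, and the one-sided p-value (default: upper tail,
#' testing for a positive association).
#'
#' @param x,y numeric vectors of equal length `n >= 3`.
#' @param alternative `"greater"` (default) or `"less"`.
#' @return list with `r`, `t`, `df`, `p`.
#' @export
pearson_one_sided <- function(x, y, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y: correlation undefined")
  r <- stats::cor(x, y)
  df <- n - 2L
  tval <- if (abs(r) >= 1) sign(r) * Inf else r * sqrt(df / (1 - r^2))
  p <- stats::pt(tval, df, lower.tail = (alternative == "less"))
  list(r = r, t = tval, df = df, p = p)
}

#' Annual effect series from a fitted trend model
#'
#' The summed effect of year (intercept + inter-annual smooth) evaluated at
#' each observed year — the model-side series validated against production
#' tonnage. Both the summed effect and the centered effect (smooth only,
#' intercept removed) are returned.
#'
#' @param fit a `cropgam_fit` from [fit_trend_model()].
#' @return an `AnnualSeries` tibble: `year`, `estimate` (summed), `se`,
#'   `centered`.
#' @export
annual_effect_series <- function(fit) {
  ec <- effect_curve(fit, "year", grid = fit$years)
  tibble::tibble(year = fit$years, estimate = ec$estimate, se = ec$se,
                 centered = ec$estimate - unname(fit$coefficients[1]))
}

#' Read a FAOSTAT-style production export
#'
#' Accepts the standard FAOSTAT CSV layout (`Area`, `Item`, `Year`, `Value`
#' columns; `Value` in tonnes), filters to the requested crops, and sums
#' production over crops within each year.
#'
#' @param path CSV path.
#' @param crops character vector of crop items to keep (default: the six
#'   major Ukrainian crops — barley, maize, wheat, rapeseed, potatoes,
#'   sunflower seed).
#' @param area optional area/country filter (default keeps all rows).
#' @return tibble with `year`, `tonnes`.
#' @export
read_production_csv <- function(path,
                                crops = c("Barley", "Maize", "Wheat",
                                          "Rapeseed", "Potatoes",
                                          "Sunflower seed"),
                                area = NULL) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("Item", "Year", "Value")
  if (!all(need %in% names(tab)))
    stop("expected FAOSTAT-style columns: Item, Year, Value")
  if (!is.null(area) && "Area" %in% names(tab))
    tab <- tab[tab$Area %in% area, ]
  tab <- tab[tab$Item %in% crops, ]
  tab |>
    dplyr::group_by(year = as.integer(.data$Year)) |>
    dplyr::summarise(tonnes = sum(.data$Value), .groups = "drop") |>
    dplyr::arrange(.data$year)
}

#' Validate a trend fit against an annual production series
#'
#' Runs the full validation sequence: Shapiro-Wilk on both series, then the
#' one-sided Pearson test for a positive relationship between the annual
#' summed year effect and production tonnage on the overlapping years.
#'
#' @param fit a `cropgam_fit` from [fit_trend_model()].
#' @param production tibble with `year` and `tonnes` (see
#'   [read_production_csv()]).
#' @return list with `years` used, `shapiro_gpp`, `shapiro_production`
#'   (each `W`, `p`) and `correlation` (`r`, `t`, `df`, `p`).
#' @export
validate_against_production <- function(fit, production) {
  eff <- annual_effect_series(fit)
  merged <- dplyr::inner_join(eff, production, by = "year")
  if (nrow(merged) < 3) stop("fewer than 3 overlapping years")
  list(years = merged$year,
       shapiro_gpp = shapiro_wilk(merged$estimate),
       shapiro_production = shapiro_wilk(merged$tonnes),
       correlation = pearson_one_sided(merged$estimate, merged$tonnes,
                                       alternative = "greater"))
}
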