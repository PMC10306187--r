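#' @title Penalized additive model fitting with AR(1) errors
#' @description
#' The estimation engine: assembles the block design for the trend and
#' event-factor models, fits penalized least squares by stable Cholesky
#' factorization of the penalized normal equations, selects smoothing
#' parameters by Gaussian restricted maximum likelihood (REML) with analytic
#' gradients in log-lambda, estimates a single global AR(1) residual
#' correlation per pixel time series, and refits on AR(1)-whitened data so
#' that generalized least squares reduces to ordinary least squares.
#' @name gam_fit
NULL

#' Model configuration
#'
#' Tunable settings for [fit_trend_model()] and [fit_event_model()].
#'
#' @param year_k basis dimension for the inter-annual spline; `NULL` (default)
#'   uses the number of unique years in the table.
#' @param month_k cyclic seasonal basis dimension (default 12, one per month).
#' @param space_k spatial Gaussian-process basis dimension (default 50),
#'   clamped to the number of distinct pixels.
#' @param space_rank_tensor rank of the spatial margin inside tensor-product
#'   interactions (default 20) to keep interaction blocks modest.
#' @param gp_range Matern range in the units of `distance`; `NULL` = half the
#'   maximum inter-pixel distance.
#' @param distance `"km"` great-circle (default) or `"degrees"`.
#' @param rho_mode AR(1) estimation: `"plugin"` (lag-1 residual
#'   autocorrelation, default), `"search"` (golden-section refinement of the
#'   whitened REML), or `"none"`.
#' @param criterion smoothing-parameter criterion, `"REML"` (default) or
#'   `"GCV"`.
#' @param bin if `TRUE`, round longitude/latitude to `bin_digits` decimals,
#'   aggregate duplicated (pixel, date) covariate rows and fit with frequency
#'   weights — a simplified covariate-discretization speed-up. AR(1)
#'   estimation is skipped when binning is on.
#' @param bin_digits decimals kept when binning coordinates (default 1).
#' @param lambda_start optional named vector of smoothing parameters used as
#'   the single optimizer start (skips the multi-start).
#' @return a list of class `cropgam_config`.
#' @export
model_config <- function(year_k = NULL, month_k = 12, space_k = 50,
                         space_rank_tensor = 20, gp_range = NULL,
                         distance = c("km", "degrees"),
                         rho_mode = c("plugin", "search", "none"),
                         criterion = c("REML", "GCV"),
                         bin = FALSE, bin_digits = 1, lambda_start = NULL) {
  structure(list(year_k = year_k, month_k = month_k, space_k = space_k,
                 space_rank_tensor = space_rank_tensor, gp_range = gp_range,
                 distance = match.arg(distance),
                 rho_mode = match.arg(rho_mode),
                 criterion = match.arg(criterion),
                 bin = bin, bin_digits = bin_digits,
                 lambda_start = lambda_start),
            class = "cropgam_config")
}

# ---- design assembly -------------------------------------------------------

#' Assemble the model design from a long table and smooth blocks
#'
#' Binds an intercept column, an optional treatment-coded event factor
#' (reference level first) and the given smooth blocks into a single design
#' matrix with a recorded column map. Column order is fixed: intercept,
#' factor, blocks in the order supplied.
#'
#' @param table a long observation table (rows define the design rows).
#' @param blocks list of `basis_block`s built on the same rows.
#' @param response numeric response vector (one per row).
#' @param event_factor optional factor (length nrow) added as a treatment
#'   dummy for its second level.
#' @param weights optional frequency weights (default all 1).
#' @return a `cropgam_design` list: `X`, `y`, `w`, `terms` (per-block column
#'   indices and penalties), `parametric` indices, `col_labels`.
#' @export
assemble_design <- function(table, blocks, response, event_factor = NULL,
                            weights = NULL) {
  n <- nrow(table)
  if (n == 0L) stop("empty table")
  if (length(response) != n) stop("response length must match table rows")
  cols <- list(matrix(1, n, 1))
  labels <- "(Intercept)"
  parametric <- 1L
  factor_col <- NULL
  if (!is.null(event_factor)) {
    f <- as.factor(event_factor)
    if (nlevels(f) != 2) stop("event factor must have exactly two levels")
    dummy <- as.numeric(f == levels(f)[2])
    cols <- c(cols, list(matrix(dummy, n, 1)))
    labels <- c(labels, paste0("war", levels(f)[2]))
    parametric <- c(parametric, 2L)
    factor_col <- 2L
  }
  terms <- list()
  p0 <- length(parametric)
  at <- p0
  for (b in blocks) {
    pj <- ncol(b$X)
    cols <- c(cols, list(b$X))
    labels <- c(labels, paste0(b$label, ".", seq_len(pj)))
    terms[[b$label]] <- list(label = b$label, cols = at + seq_len(pj),
                             pen = b$pen, block = b)
    at <- at + pj
  }
  X <- do.call(cbind, cols)
  colnames(X) <- labels
  structure(list(X = X, y = as.numeric(response),
                 w = if (is.null(weights)) rep(1, n) else as.numeric(weights),
                 terms = terms, parametric = parametric,
                 factor_col = factor_col, col_labels = labels, n = n),
            class = "cropgam_design")
}

# precompute the sufficient statistics and penalty bookkeeping reused by
# every REML evaluation
design_suffstat <- function(design) {
  w <- design$w
  sw <- sqrt(w)
  Xw <- design$X * sw
  out <- list(
    XtX = crossprod(Xw),
    Xty = crossprod(design$X, w * design$y),
    yty = sum(w * design$y^2),
    n = sum(w), p = ncol(design$X))
  # per-term penalty bookkeeping: precompute ranks / log-determinants where
  # they do not depend on lambda (single-penalty terms)
  pens <- list(); meta <- list(); idx <- 0L
  for (tm in design$terms) {
    single <- length(tm$pen) == 1L
    ev1 <- NULL
    if (single) {
      ev <- eigen(tm$pen[[1]], symmetric = TRUE, only.values = TRUE)$values
      pos <- ev > max(ev) * 1e-9
      ev1 <- list(rank = sum(pos), ldet = sum(log(ev[pos])))
    }
    for (l in seq_along(tm$pen)) {
      idx <- idx + 1L
      pens[[idx]] <- list(term = tm$label, cols = tm$cols, S = tm$pen[[l]],
                          name = if (length(tm$pen) == 1L) tm$label
                                 else sprintf("%s.m%d", tm$label, l))
    }
    meta[[tm$label]] <- list(cols = tm$cols, single = single, ev1 = ev1,
                             pen_ids = (idx - length(tm$pen) + 1L):idx)
  }
  out$pens <- pens
  out$term_meta <- meta
  out
}

# penalized cross-product matrix A = X'WX + sum lambda_l S_l
build_A <- function(ss, lambda) {
  A <- ss$XtX
  for (l in seq_along(ss$pens)) {
    pb <- ss$pens[[l]]
    A[pb$cols, pb$cols] <- A[pb$cols, pb$cols] + lambda[l] * pb$S
  }
  A
}

# log pseudo-determinant and rank of the total penalty, plus (optionally) its
# block-wise pseudo-inverse traces against each component penalty
penalty_logdet <- function(ss, lambda, want_grad = FALSE) {
  ldet <- 0; rank <- 0L
  grad <- numeric(length(ss$pens))
  for (tmname in names(ss$term_meta)) {
    tm <- ss$term_meta[[tmname]]
    if (tm$single) {
      l <- tm$pen_ids
      ldet <- ldet + tm$ev1$rank * log(lambda[l]) + tm$ev1$ldet
      rank <- rank + tm$ev1$rank
      if (want_grad) grad[l] <- tm$ev1$rank / lambda[l]
    } else {
      Sl <- 0
      for (l in tm$pen_ids) Sl <- Sl + lambda[l] * ss$pens[[l]]$S
      eg <- eigen(symz(Sl), symmetric = TRUE)
      pos <- eg$values > max(eg$values) * 1e-9
      ldet <- ldet + sum(log(eg$values[pos]))
      rank <- rank + sum(pos)
      if (want_grad) {
        U <- eg$vectors[, pos, drop = FALSE]
        di <- 1 / eg$values[pos]
        for (l in tm$pen_ids) {
          M <- crossprod(U, ss$pens[[l]]$S %*% U)
          grad[l] <- sum(diag(M) * di)
        }
      }
    }
  }
  list(ldet = ldet, rank = rank, grad = grad)
}

# ---- penalized least squares ----------------------------------------------

#' Fit the penalized least-squares problem at fixed smoothing parameters
#'
#' Solves `min ||sqrt(w)(y - X b)||^2 + sum_l lambda_l b' S_l b` by Cholesky
#' factorization of the penalized normal equations, with a small ridge
#' fallback (`1e-10 tr(X'X)/p`) if the penalized system is singular. The
#' posterior covariance is `phi (X'WX + S_lambda)^{-1}` with
#' `phi = RSS / (n - edf)`.
#'
#' @param design a `cropgam_design` from [assemble_design()].
#' @param lambda named or positional vector of smoothing parameters, one per
#'   penalty (terms in design order; tensor terms contribute one per margin).
#'   A scalar is recycled.
#' @param ss optional precomputed sufficient statistics (internal reuse).
#' @return a list of class `cropgam_pls`: `coefficients`, `Vp`, `phi`,
#'   `edf` (named per term, parametric dof included under `"parametric"`),
#'   `edf_total`, `rss`, `fitted`, `lambda`.
#' @export
fit_penalized <- function(design, lambda, ss = NULL) {
  if (is.null(ss)) ss <- design_suffstat(design)
  nl <- length(ss$pens)
  if (length(lambda) == 1L && nl != 1L) lambda <- rep(lambda, nl)
  if (length(lambda) != nl)
    stop(sprintf("expected %d smoothing parameters, got %d", nl, length(lambda)))
  if (any(lambda < 0)) stop("smoothing parameters must be >= 0")
  if (length(lambda) == 0L || all(lambda == 0)) {
    qx <- qr(design$X * sqrt(design$w))
    if (qx$rank < ncol(design$X)) {
      bad <- design$col_labels[qx$pivot[(qx$rank + 1):ncol(design$X)]]
      stop(sprintf("design is rank deficient with all lambda = 0; collinear columns: %s",
                   paste(bad, collapse = ", ")))
    }
  }
  A <- build_A(ss, lambda)
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    ridge <- 1e-10 * sum(diag(ss$XtX)) / ss$p
    ch <- chol(A + diag(ridge, ss$p))
  }
  beta <- backsolve(ch, forwardsolve(t(ch), ss$Xty))
  Ainv <- chol2inv(ch)
  rss <- max(ss$yty - 2 * sum(beta * ss$Xty) + sum(beta * (ss$XtX %*% beta)), 0)
  hat_diag <- rowSums(Ainv * ss$XtX)        # diag of (A^-1 X'WX)
  edf_total <- sum(hat_diag)
  edf <- c(parametric = sum(hat_diag[design$parametric]))
  for (tm in design$terms) edf[tm$label] <- sum(hat_diag[tm$cols])
  phi <- rss / max(ss$n - edf_total, 1)
  pen_q <- 0
  for (l in seq_along(ss$pens)) {
    pb <- ss$pens[[l]]
    pen_q <- pen_q + lambda[l] * sum(beta[pb$cols] * (pb$S %*% beta[pb$cols]))
  }
  beta <- as.numeric(beta)
  names(beta) <- design$col_labels
  AX <- Ainv %*% ss$XtX
  Ve <- phi * (AX %*% Ainv)                 # sampling covariance of beta-hat
  structure(list(coefficients = beta, Vp = phi * Ainv, Ve = symz(Ve), phi = phi,
                 edf = edf, edf_total = edf_total, rss = rss,
                 penalty = pen_q,
                 fitted = as.numeric(design$X %*% beta),
                 lambda = stats::setNames(lambda, vapply(ss$pens, `[[`, "", "name")),
                 hat_diag = hat_diag, n = ss$n),
            class = "cropgam_pls")
}

# ---- REML smoothing-parameter selection ------------------------------------

# -2 * restricted log-likelihood with phi profiled out, and its gradient in
# log(lambda). D = RSS + penalty; M0 = p - rank(S_lambda) unpenalized
# directions; phi_hat = D / (n - M0).
reml_score <- function(loglam, ss, want_grad = FALSE) {
  lambda <- exp(loglam)
  A <- build_A(ss, lambda)
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    ridge <- 1e-10 * sum(diag(ss$XtX)) / ss$p
    ch <- chol(A + diag(ridge, ss$p))
  }
  beta <- backsolve(ch, forwardsolve(t(ch), ss$Xty))
  rss <- max(ss$yty - 2 * sum(beta * ss$Xty) + sum(beta * (ss$XtX %*% beta)), 1e-300)
  pl <- penalty_logdet(ss, lambda, want_grad = want_grad)
  pen_terms <- numeric(length(ss$pens))
  for (l in seq_along(ss$pens)) {
    pb <- ss$pens[[l]]
    pen_terms[l] <- sum(beta[pb$cols] * (pb$S %*% beta[pb$cols]))
  }
  D <- rss + sum(lambda * pen_terms)
  M0 <- ss$p - pl$rank
  nd <- ss$n - M0
  phi <- D / nd
  ldetA <- 2 * sum(log(diag(ch)))
  val <- nd * (log(2 * pi * phi) + 1) + ldetA - pl$ldet
  if (!want_grad) return(list(value = val))
  Ainv <- chol2inv(ch)
  grad <- numeric(length(ss$pens))
  for (l in seq_along(ss$pens)) {
    pb <- ss$pens[[l]]
    trAinvS <- sum(Ainv[pb$cols, pb$cols] * pb$S)
    # d(-2lr)/dlambda: envelope for D, trace terms for the determinants
    dl <- (nd / D) * pen_terms[l] + trAinvS - pl$grad[l]
    grad[l] <- dl * lambda[l]              # chain rule to log-lambda
  }
  list(value = val, grad = grad)
}

gcv_score <- function(loglam, ss, gamma = 1) {
  lambda <- exp(loglam)
  A <- build_A(ss, lambda)
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) ch <- chol(A + diag(1e-10 * sum(diag(ss$XtX)) / ss$p, ss$p))
  beta <- backsolve(ch, forwardsolve(t(ch), ss$Xty))
  rss <- max(ss$yty - 2 * sum(beta * ss$Xty) + sum(beta * (ss$XtX %*% beta)), 1e-300)
  edf <- sum(chol2inv(ch) * ss$XtX)
  ss$n * rss / (ss$n - gamma * edf)^2
}

#' Select smoothing parameters by restricted maximum likelihood
#'
#' Maximizes the Gaussian restricted likelihood (scale profiled out) over
#' log smoothing parameters with L-BFGS-B and analytic gradients. Unless a
#' single `start` is supplied, the optimizer is multi-started from all
#' smoothing parameters equal to 1e-3, 1 and 1e3, keeping the best optimum.
#'
#' @param design a `cropgam_design`.
#' @param start optional vector of starting smoothing parameters (one value
#'   or one per penalty).
#' @param criterion `"REML"` (default) or `"GCV"` (numeric gradient).
#' @param maxit optimizer iteration cap per start (default 100).
#' @param ss optional precomputed sufficient statistics.
#' @return list with `lambda` (named), `score`, `convergence` (0 = clean),
#'   `criterion`.
#' @export
select_lambda_reml <- function(design, start = NULL, criterion = c("REML", "GCV"),
                               maxit = 100, ss = NULL) {
  criterion <- match.arg(criterion)
  if (is.null(ss)) ss <- design_suffstat(design)
  nl <- length(ss$pens)
  if (nl == 0L) stop("no penalties to select smoothing parameters for")
  starts <- if (!is.null(start)) {
    list(log(rep(as.numeric(start), length.out = nl)))
  } else {
    lapply(c(1e-3, 1, 1e3), function(s) rep(log(s), nl))
  }
  fn <- if (criterion == "REML") {
    function(ll) reml_score(ll, ss)$value
  } else {
    function(ll) gcv_score(ll, ss)
  }
  gr <- if (criterion == "REML") function(ll) reml_score(ll, ss, want_grad = TRUE)$grad
        else NULL
  best <- NULL
  conv <- 0L
  for (s0 in starts) {
    op <- stats::optim(s0, fn, gr, method = "L-BFGS-B",
                       lower = rep(-30, nl), upper = rep(30, nl),
                       control = list(maxit = maxit, factr = 1e9))
    if (is.null(best) || op$value < best$value) best <- op
  }
  if (best$convergence != 0) {
    warning("smoothing-parameter optimization did not fully converge; returning best found")
    conv <- best$convergence
  }
  lambda <- exp(best$par)
  names(lambda) <- vapply(ss$pens, `[[`, "", "name")
  list(lambda = lambda, score = best$value, convergence = conv,
       criterion = criterion)
}

# ---- AR(1) machinery -------------------------------------------------------

#' Plug-in AR(1) correlation from within-pixel residuals
#'
#' Pools the lag-1 autocovariance of residuals over pixels: for each pixel
#' time series (date-ordered), accumulate `sum(r[t] r[t-1])` and `sum(r^2)`;
#' the estimate is their pooled ratio. Pixels with fewer than 3 epochs are
#' skipped. `method = "search"` refines the plug-in value by golden-section
#' search of rho in (0, 0.99) minimizing the REML score of the whitened fit.
#'
#' @param residuals numeric residual vector, one per table row.
#' @param table the long table the model was fitted to (must be sorted by
#'   pixel then date, as the fitting functions arrange it).
#' @param method `"plugin"` (default) or `"search"`.
#' @param design,lambda required for `method = "search"`: the design and the
#'   smoothing parameters at which each candidate rho is refitted.
#' @return the estimated correlation (scalar in (-0.99, 0.99)).
#' @export
estimate_rho <- function(residuals, table, method = c("plugin", "search"),
                         design = NULL, lambda = NULL) {
  method <- match.arg(method)
  key <- pixel_key(table)
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= 3L
  if (!any(keep)) stop("no pixel has >= 3 epochs; cannot estimate AR(1) correlation")
  if (stats::sd(residuals) < 1e-12 * (1 + mean(abs(residuals))))
    stop("degenerate residuals (constant); AR(1) correlation undefined")
  num <- 0; den <- 0
  for (g in which(keep)) {
    rr <- residuals[starts[g]:ends[g]]
    num <- num + sum(rr[-1] * rr[-length(rr)])
    den <- den + sum(rr^2)
  }
  if (den <= 0) stop("degenerate residuals; AR(1) correlation undefined")
  rho <- max(-0.98, min(0.98, num / den))
  if (method == "plugin") return(rho)
  if (is.null(design) || is.null(lambda))
    stop("method = 'search' needs `design` and `lambda`")
  obj <- function(rh) {
    wd <- whiten_ar1(design, table, rh)
    reml_score(log(lambda), design_suffstat(wd))$value
  }
  stats::optimize(obj, c(0.001, 0.99), tol = 1e-3)$minimum
}

#' AR(1) whitening transform
#'
#' Applies the exact AR(1) decorrelation row transform within each pixel's
#' date-ordered series: the first row of a series is scaled by
#' `sqrt(1 - rho^2)`, every later row becomes `row_t - rho row_{t-1}`. The
#' same transform is applied to the design and the response, so ordinary
#' least squares on the transformed data equals generalized least squares
#' under the AR(1) correlation.
#'
#' @param design a `cropgam_design`.
#' @param table the long table defining pixel grouping and date order.
#' @param rho AR(1) correlation, `|rho| < 1`.
#' @return a new `cropgam_design` with transformed `X` and `y`.
#' @export
whiten_ar1 <- function(design, table, rho) {
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  key <- pixel_key(table)
  r <- rle(key)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  d <- as.Date(table$date)
  for (g in seq_along(starts)) {
    if (r$lengths[g] > 1L &&
        is.unsorted(d[starts[g]:ends[g]], strictly = TRUE))
      stop(sprintf("pixel group %d is not strictly date-ordered", g))
  }
  if (rho == 0) return(design)
  n <- nrow(design$X)
  first <- logical(n); first[starts] <- TRUE
  lag_idx <- c(1L, seq_len(n - 1L))
  X <- design$X - rho * design$X[lag_idx, , drop = FALSE]
  y <- design$y - rho * design$y[lag_idx]
  s <- sqrt(1 - rho^2)
  X[first, ] <- s * design$X[first, , drop = FALSE]
  y[first] <- s * design$y[first]
  out <- design
  out$X <- X
  out$y <- y
  out
}

# ---- model pipelines -------------------------------------------------------

sort_long_table <- function(table) {
  o <- order(pixel_key(table), as.Date(table$date))
  table[o, , drop = FALSE]
}

bin_table <- function(table, value_name, digits) {
  tb <- table
  tb$longitude <- round(tb$longitude, digits)
  tb$latitude <- round(tb$latitude, digits)
  grp <- paste(sprintf("%.6f", tb$longitude), sprintf("%.6f", tb$latitude),
               tb$year, tb$month, if ("war" %in% names(tb)) tb$war else "")
  agg <- tb |>
    dplyr::mutate(.grp = grp) |>
    dplyr::group_by(.data$.grp) |>
    dplyr::summarise(dplyr::across(dplyr::any_of(c("longitude", "latitude", "year", "month")),
                                   dplyr::first),
                     date = dplyr::first(.data$date),
                     war = if ("war" %in% names(tb)) dplyr::first(.data$war) else NULL,
                     .value = mean(.data[[value_name]]),
                     .w = dplyr::n(), .groups = "drop")
  agg[[value_name]] <- agg$.value
  agg$.value <- NULL
  agg
}

build_trend_blocks <- function(table, config) {
  years <- sort(unique(table$year))
  ky <- if (is.null(config$year_k)) length(years) else config$year_k
  n_px <- nrow(unique(cbind(table$longitude, table$latitude)))
  ks <- min(config$space_k, n_px)
  yr <- crs_basis(table$year, k = ky, constrain = TRUE, var = "year")
  mo <- cyclic_basis(table$month, k = config$month_k, period = 12, origin = 1,
                     constrain = TRUE, var = "month")
  sp <- gp_basis(table$longitude, table$latitude, k = ks,
                 range = config$gp_range, distance = config$distance,
                 constrain = TRUE)
  sp_t <- gp_basis(table$longitude, table$latitude, k = ks,
                   range = config$gp_range, distance = config$distance,
                   rank = min(config$space_rank_tensor, ks),
                   constrain = TRUE)
  list(year = yr, month = mo, space = sp,
       ym = tensor_interaction(yr, mo),
       sy = tensor_interaction(sp_t, yr))
}

finalize_fit <- function(design, pls, sel, rho, table, config, model,
                         value_name) {
  med <- function(x) stats::median(x)
  px <- unique(cbind(table$longitude, table$latitude))
  hull <- grDevices::chull(px[, 1], px[, 2])
  structure(list(
    model = model,
    coefficients = pls$coefficients,
    Vp = pls$Vp, Ve = pls$Ve, phi = pls$phi,
    lambda = pls$lambda, rho = rho,
    edf = pls$edf, edf_total = pls$edf_total,
    rss = pls$rss, reml = sel$score, criterion = sel$criterion,
    n = pls$n, df_residual = pls$n - pls$edf_total,
    design_terms = design$terms, parametric = design$parametric,
    factor_col = design$factor_col, col_labels = design$col_labels,
    conditioning = list(year = med(table$year), month = med(table$month),
                        longitude = med(table$longitude),
                        latitude = med(table$latitude)),
    years = sort(unique(table$year)),
    train_range = list(year = range(table$year), month = range(table$month),
                       longitude = range(table$longitude),
                       latitude = range(table$latitude)),
    pixel_hull = px[hull, , drop = FALSE],
    value_name = value_name,
    config = config), class = "cropgam_fit")
}

#' @export
print.cropgam_fit <- function(x, ...) {
  cat(sprintf("cropgam %s model: n = %d, edf = %.1f, phi = %.4g, rho = %.3f\n",
              x$model, x$n, x$edf_total, x$phi, x$rho))
  if (!is.null(x$factor_col)) {
    est <- x$coefficients[x$factor_col]
    se <- sqrt(x$Ve[x$factor_col, x$factor_col])
    cat(sprintf("  step change (post - pre): %.4f (SE %.4f)\n", est, se))
  }
  cat("  per-term edf:\n")
  print(round(x$edf, 2))
  invisible(x)
}

run_pipeline_fit <- function(table, blocks, config, event_factor, model,
                             value_name, weights = NULL) {
  design <- assemble_design(table, blocks, response = table[[value_name]],
                            event_factor = event_factor, weights = weights)
  ss <- design_suffstat(design)
  sel <- select_lambda_reml(design, start = config$lambda_start,
                            criterion = config$criterion, ss = ss)
  pls <- fit_penalized(design, sel$lambda, ss = ss)
  rho <- 0
  if (config$rho_mode != "none" && is.null(weights)) {
    resid0 <- design$y - pls$fitted
    rho <- tryCatch(
      estimate_rho(resid0, table,
                   method = if (config$rho_mode == "search") "search" else "plugin",
                   design = design, lambda = sel$lambda),
      error = function(e) { warning(conditionMessage(e)); 0 })
    if (rho != 0) {
      wdesign <- whiten_ar1(design, table, rho)
      wss <- design_suffstat(wdesign)
      sel <- select_lambda_reml(wdesign, start = sel$lambda,
                                criterion = config$criterion, ss = wss)
      pls <- fit_penalized(wdesign, sel$lambda, ss = wss)
    }
  }
  finalize_fit(design, pls, sel, rho, table, config, model, value_name)
}

#' Fit the seasonal-trend decomposition model
#'
#' The long-run model: response = intercept + smooth(year) + cyclic
#' smooth(month) + GP smooth(lon, lat) + tensor(year, month) +
#' tensor(space, year), with AR(1) errors within each pixel's time series.
#' Smoothing parameters are chosen by REML on the independent-error fit, the
#' AR(1) correlation is estimated from its residuals, and the model is refit
#' on whitened data.
#'
#' @param table a long table with columns `longitude`, `latitude`, `date`,
#'   `year`, `month` and the response (see [add_calendar_columns()]).
#' @param config a [model_config()].
#' @param value_name response column name (default `"gpp"`).
#' @return a `cropgam_fit`.
#' @export
fit_trend_model <- function(table, config = model_config(),
                            value_name = "gpp") {
  req <- c("longitude", "latitude", "date", "year", "month", value_name)
  miss <- setdiff(req, names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  table <- sort_long_table(table)
  weights <- NULL
  if (isTRUE(config$bin)) {
    table <- bin_table(table, value_name, config$bin_digits)
    table <- sort_long_table(table)
    weights <- table$.w
    config$rho_mode <- "none"
  }
  blocks <- build_trend_blocks(table, config)
  run_pipeline_fit(table, blocks, config, event_factor = NULL,
                   model = "trend", value_name = value_name,
                   weights = weights)
}

#' Fit the pre/post event step-change model
#'
#' The intervention model: response = intercept + war factor (treatment
#' coded, `pre` as reference) + cyclic month smooth per war level + spatial
#' GP smooth per war level + tensor(space, month) per war level, with AR(1)
#' errors. After the seasonal and spatial structure is absorbed by the
#' level-specific smooths, the factor coefficient directly estimates the
#' post-event step change in the response, and its standard error comes from
#' the posterior covariance of the whitened fit.
#'
#' @inheritParams fit_trend_model
#' @return a `cropgam_fit` whose `war` coefficient is the step-change
#'   estimate; see [event_effect_test()].
#' @export
fit_event_model <- function(table, config = model_config(),
                            value_name = "gpp") {
  req <- c("longitude", "latitude", "date", "year", "month", "war", value_name)
  miss <- setdiff(req, names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         if ("war" %in% miss) " (run label_event() first)" else "")
  table <- sort_long_table(table)
  table$war <- factor(as.character(table$war), levels = c("pre", "post"))
  weights <- NULL
  if (isTRUE(config$bin)) {
    table <- bin_table(table, value_name, config$bin_digits)
    table <- sort_long_table(table)
    table$war <- factor(as.character(table$war), levels = c("pre", "post"))
    weights <- table$.w
    config$rho_mode <- "none"
  }
  n_px <- nrow(unique(cbind(table$longitude, table$latitude)))
  ks <- min(config$space_k, n_px)
  mo_c <- cyclic_basis(table$month, k = config$month_k, period = 12,
                       origin = 1, constrain = TRUE, var = "month")
  sp_c <- gp_basis(table$longitude, table$latitude, k = ks,
                   range = config$gp_range, distance = config$distance,
                   constrain = TRUE)
  sp_t <- gp_basis(table$longitude, table$latitude, k = ks,
                   range = config$gp_range, distance = config$distance,
                   rank = min(config$space_rank_tensor, ks), constrain = TRUE)
  blocks <- c(by_factor(mo_c, table$war),
              by_factor(sp_c, table$war),
              by_factor(tensor_interaction(sp_t, mo_c), table$war))
  run_pipeline_fit(table, blocks, config, event_factor = table$war,
                   model = "event", value_name = value_name,
                   weights = weights)
}

# ---- prediction ------------------------------------------------------------

# full design matrix at new data; columns for terms not in `terms` are zeroed
# (NULL keeps everything)
predict_design <- function(fit, newdata, terms = NULL) {
  n <- nrow(newdata)
  X <- matrix(0, n, length(fit$col_labels))
  colnames(X) <- fit$col_labels
  X[, 1] <- 1
  if (!is.null(fit$factor_col)) {
    w <- if ("war" %in% names(newdata)) as.character(newdata$war) else "pre"
    X[, fit$factor_col] <- as.numeric(w == "post")
  }
  for (tm in fit$design_terms) X[, tm$cols] <- tm$block$eval(newdata)
  if (!is.null(terms)) {
    keep <- fit$parametric
    for (lb in terms) {
      hit <- vapply(fit$design_terms,
                    function(tm) grepl(lb, tm$label, fixed = TRUE), logical(1))
      if (!any(hit)) stop(sprintf("no term matching '%s' in the fit", lb))
      for (tm in fit$design_terms[hit]) keep <- c(keep, tm$cols)
    }
    drop <- setdiff(seq_along(fit$col_labels), keep)
    X[, drop] <- 0
  }
  X
}

# linear predictor + delta-method SE for a prediction design
predict_with_se <- function(fit, X) {
  est <- as.numeric(X %*% fit$coefficients)
  se <- sqrt(pmax(rowSums((X %*% fit$Vp) * X), 0))
  list(estimate = est, se = se)
}
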