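test_that("design assembly fixes column order and is deterministic", {
  set.seed(10)
  n <- 150
  tab <- tibble::tibble(x = runif(n, 0, 10), month = sample(1:12, n, TRUE))
  y <- rnorm(n)
  blocks <- list(crs_basis(tab$x, k = 6, var = "x"),
                 cyclic_basis(tab$month, k = 8))
  d <- assemble_design(tab, blocks, y)
  expect_equal(ncol(d$X), 1L + 5L + 7L)     # intercept + (k-1) per smooth
  expect_equal(d$col_labels[1], "(Intercept)")
  f <- factor(rep(c("pre", "post"), length.out = n), levels = c("pre", "post"))
  d2 <- assemble_design(tab, blocks, y, event_factor = f)
  expect_equal(ncol(d2$X), ncol(d$X) + 1L)
  expect_equal(d2$col_labels[2], "warpost")
  d3 <- assemble_design(tab, blocks, y)
  expect_identical(d$X, d3$X)
  expect_error(assemble_design(tab[0, ], blocks, numeric(0)), "empty")
})

test_that("zero-penalty fit equals direct least squares and flags collinearity", {
  set.seed(11)
  n <- 120
  tab <- tibble::tibble(x = runif(n, 0, 10))
  y <- sin(tab$x) + rnorm(n, 0, 0.2)
  b <- crs_basis(tab$x, k = 8, var = "x")
  d <- assemble_design(tab, list(b), y)
  f0 <- fit_penalized(d, 0)
  beta_ols <- qr.solve(crossprod(d$X), crossprod(d$X, y))  # oracle
  expect_lt(max(abs(f0$coefficients - beta_ols)), 1e-8)
  # duplicated column -> rank-deficient error naming the culprit
  d_bad <- d
  d_bad$X <- cbind(d$X, d$X[, 2])
  colnames(d_bad$X)[ncol(d_bad$X)] <- "dup_col"
  d_bad$col_labels <- colnames(d_bad$X)
  expect_error(fit_penalized(d_bad, 0), "rank deficient")
})

test_that("the infinite-penalty limit removes all penalized structure", {
  set.seed(12)
  n <- 200
  tab <- tibble::tibble(x = runif(n, 0, 10), month = sample(1:12, n, TRUE))
  y <- sin(tab$x) + rnorm(n)
  # cyclic + GP penalties are full rank after centering: contributions vanish
  cb <- cyclic_basis(tab$month, k = 12)
  d <- assemble_design(tab, list(cb), y)
  f <- fit_penalized(d, 1e12)
  expect_lt(max(abs(d$X[, -1] %*% f$coefficients[-1])), 1e-6)
  expect_equal(unname(f$coefficients[1]), mean(y), tolerance = 1e-8)
  # the CRS penalty keeps its linear null space: the limit is the best line
  bb <- crs_basis(tab$x, k = 8, var = "x")
  d2 <- assemble_design(tab, list(bb), y)
  f2 <- fit_penalized(d2, 1e12)
  line <- stats::lm(y ~ x, data = tab)
  expect_equal(unname(drop(cbind(1, bb$eval(tab)) %*% f2$coefficients)),
               unname(fitted(line)), tolerance = 1e-5)
})

test_that("a known smooth signal is recovered at moderate penalty", {
  set.seed(13)
  n <- 400
  x <- runif(n, 0, 1)
  f_true <- function(x) 2 * x^3 - 3 * x^2 + x
  y <- f_true(x) + rnorm(n, 0, 0.01)
  tab <- tibble::tibble(x = x)
  b <- crs_basis(x, k = 10, var = "x")
  d <- assemble_design(tab, list(b), y)
  fit <- fit_penalized(d, 0.1)
  grid <- seq(0.02, 0.98, length.out = 50)
  fhat <- drop(cbind(1, b$eval(data.frame(x = grid))) %*% fit$coefficients)
  expect_lt(sqrt(mean((fhat - f_true(grid))^2)), 0.05)
})

test_that("REML selects heavy smoothing for noise and matches a grid-search oracle for signal", {
  set.seed(14)
  n <- 300
  tab <- tibble::tibble(x = runif(n, 0, 10))
  b <- crs_basis(tab$x, k = 8, var = "x")
  # pure noise: the smooth should be shrunk to (near) its null space
  d_noise <- assemble_design(tab, list(b), rnorm(n))
  sel_n <- select_lambda_reml(d_noise)
  f_n <- fit_penalized(d_noise, sel_n$lambda)
  expect_lt(f_n$edf[b$label], 1.5)
  # strong signal: optimizer edf within 1 of a brute-force log-lambda grid
  y <- sin(tab$x) + rnorm(n, 0, 0.05)
  d_sig <- assemble_design(tab, list(b), y)
  sel_s <- select_lambda_reml(d_sig)
  ssd <- cropgam:::design_suffstat(d_sig)
  grid <- 10^seq(-6, 6, by = 0.05)
  scores <- vapply(grid, function(l) cropgam:::reml_score(log(l), ssd)$value,
                   numeric(1))
  f_opt <- fit_penalized(d_sig, sel_s$lambda)
  f_grid <- fit_penalized(d_sig, grid[which.min(scores)])
  expect_lt(abs(f_opt$edf[b$label] - f_grid$edf[b$label]), 1)
  # lambda is invariant to rescaling the response
  sel_scaled <- select_lambda_reml(assemble_design(tab, list(b), 10 * y))
  expect_equal(log(sel_scaled$lambda), log(sel_s$lambda), tolerance = 0.05)
})

test_that("plug-in rho is calibrated on white and AR(1) residuals", {
  wn <- ar1_residual_table(n_px = 200, n_t = 50, rho = 0, seed = 21)
  rho_wn <- estimate_rho(wn$residuals, wn$table)
  expect_gt(rho_wn, -0.05); expect_lt(rho_wn, 0.05)
  ar <- ar1_residual_table(n_px = 200, n_t = 50, rho = 0.6, seed = 22)
  rho_ar <- estimate_rho(ar$residuals, ar$table)
  expect_gt(rho_ar, 0.55); expect_lt(rho_ar, 0.65)
  expect_error(estimate_rho(rep(1, nrow(wn$table)), wn$table), "degenerate")
})

test_that("AR(1) whitening is identity at rho 0, decorrelates at the true rho, and scales singletons", {
  ar <- ar1_residual_table(n_px = 100, n_t = 40, rho = 0.6, seed = 23)
  tab <- ar$table
  tab$gpp <- ar$residuals
  d <- assemble_design(tab, list(), tab$gpp)
  expect_identical(whiten_ar1(d, tab, 0)$X, d$X)
  wd <- whiten_ar1(d, tab, 0.6)
  res_w <- wd$y - wd$X %*% qr.solve(crossprod(wd$X), crossprod(wd$X, wd$y))
  rho_after <- estimate_rho(as.numeric(res_w), tab)
  expect_gt(rho_after, -0.05); expect_lt(rho_after, 0.05)
  # single-observation groups only get the sqrt(1 - rho^2) scaling
  tab1 <- tibble::tibble(longitude = 30 + 1:5, latitude = 47,
                         date = as.Date("2020-01-01"), gpp = rnorm(5))
  d1 <- assemble_design(tab1, list(), tab1$gpp)
  w1 <- whiten_ar1(d1, tab1, 0.6)
  expect_equal(w1$y, sqrt(1 - 0.36) * d1$y)
  # unordered groups are an error
  tab_bad <- tab[c(2, 1, 3:nrow(tab)), ]
  d_bad <- assemble_design(tab_bad, list(), tab_bad$gpp)
  expect_error(whiten_ar1(d_bad, tab_bad, 0.3), "date-ordered")
})

test_that("whitened OLS equals brute-force GLS with the explicit AR(1) covariance", {
  set.seed(24)
  n_px <- 8; n_t <- 25; n <- n_px * n_t; rho <- 0.45
  tab <- tibble::tibble(
    longitude = rep(30 + (1:n_px) * 0.1, each = n_t), latitude = 47,
    date = rep(seq(as.Date("2021-01-01"), by = 8, length.out = n_t), n_px))
  x <- runif(n, 0, 10)
  tab$x <- x
  y <- 1 + sin(x) + rnorm(n)
  b <- crs_basis(x, k = 6, var = "x")
  d <- assemble_design(tab, list(b), y)
  wd <- whiten_ar1(d, tab, rho)
  lam <- 2.5
  fw <- fit_penalized(wd, lam)
  # oracle: explicit per-pixel AR(1) correlation, dense GLS normal equations
  Sig1 <- rho^abs(outer(1:n_t, 1:n_t, "-"))
  Sinv <- solve(Sig1)
  XtSX <- 0; XtSy <- 0
  for (g in seq_len(n_px)) {
    idx <- (g - 1) * n_t + 1:n_t
    XtSX <- XtSX + t(d$X[idx, ]) %*% Sinv %*% d$X[idx, ]
    XtSy <- XtSy + t(d$X[idx, ]) %*% Sinv %*% y[idx]
  }
  S_full <- matrix(0, ncol(d$X), ncol(d$X))
  tm <- d$terms[[1]]
  S_full[tm$cols, tm$cols] <- lam * tm$pen[[1]]
  # the whitening transform T satisfies T'T = (1 - rho^2) Sigma^{-1}, so the
  # whitened penalized fit solves ((1-rho^2) X'S^-1X + lam S)b = (1-rho^2) X'S^-1y
  beta_gls <- solve(XtSX * (1 - rho^2) + S_full, XtSy * (1 - rho^2))
  expect_lt(max(abs(fw$coefficients - beta_gls)), 1e-8)
  # unpenalized case: plain GLS equality
  f0 <- fit_penalized(wd, 0)
  beta_gls0 <- solve(XtSX, XtSy)
  expect_lt(max(abs(f0$coefficients - beta_gls0)), 1e-8)
})

test_that("total edf equals the trace of the influence matrix", {
  set.seed(25)
  n <- 150
  tab <- tibble::tibble(x = runif(n, 0, 10), month = sample(1:12, n, TRUE))
  y <- sin(tab$x) + rnorm(n, 0, 0.3)
  blocks <- list(crs_basis(tab$x, k = 7, var = "x"),
                 cyclic_basis(tab$month, k = 8))
  d <- assemble_design(tab, blocks, y)
  f <- fit_penalized(d, c(1, 5))
  A <- cropgam:::build_A(cropgam:::design_suffstat(d), c(1, 5))
  H <- d$X %*% solve(A) %*% t(d$X)
  expect_equal(f$edf_total, sum(diag(H)), tolerance = 1e-6)
  expect_equal(f$edf_total, sum(f$edf), tolerance = 1e-6)
})

test_that("the fitted seasonal smooth matches an independent mgcv fit", {
  set.seed(26)
  n <- 500
  m <- runif(n, 1, 13)
  y <- 1.2 * sin(2 * pi * m / 12) + rnorm(n, 0, 0.3)
  tab <- tibble::tibble(month = m)
  blk <- cyclic_basis(m, k = 12, origin = 1)
  d <- assemble_design(tab, list(blk), y)
  sel <- select_lambda_reml(d)
  fit <- fit_penalized(d, sel$lambda)
  grid <- data.frame(month = seq(1, 12.99, by = 0.01))
  ours <- drop(cbind(1, blk$eval(grid)) %*% fit$coefficients)
  mg <- mgcv::gam(y ~ s(month, bs = "cc", k = 12), data = tab,
                  method = "REML")
  theirs <- as.numeric(mgcv::predict.gam(mg, grid))
  expect_gt(cor(ours, theirs), 0.999)
  expect_lt(sqrt(mean((ours - theirs)^2)), 0.05)
})

test_that("event-model fits are reproducible and binning moves the step estimate by < 0.5 SE", {
  sim <- small_event_sim()
  cfg <- small_model_config(rho_mode = "none")
  f1 <- fit_event_model(sim$table, cfg)
  f2 <- fit_event_model(sim$table, cfg)
  expect_identical(f1$coefficients, f2$coefficients)
  fb <- fit_event_model(sim$table, small_model_config(rho_mode = "none",
                                                      bin = TRUE))
  t1 <- event_effect_test(f1)
  expect_lt(abs(fb$coefficients[fb$factor_col] - t1$estimate), 0.5 * t1$se)
})

test_that("optional estimation modes run: rho search, GCV, and extrapolation warnings", {
  sim <- small_event_sim()
  fit_s <- fit_event_model(sim$table, small_model_config(rho_mode = "search"))
  expect_gt(fit_s$rho, 0)
  expect_lt(fit_s$rho, 0.99)
  # GCV as the alternative smoothing criterion
  set.seed(27)
  tab <- tibble::tibble(x = runif(250, 0, 10))
  y <- sin(tab$x) + rnorm(250, 0, 0.2)
  b <- crs_basis(tab$x, k = 8, var = "x")
  d <- assemble_design(tab, list(b), y)
  sel <- select_lambda_reml(d, criterion = "GCV")
  f <- fit_penalized(d, sel$lambda)
  expect_true(all(sel$lambda > 0))
  expect_gt(f$edf[b$label], 2)   # GCV keeps real structure on strong signal
  # effect-curve grids beyond the training years warn and extrapolate
  fit_t <- small_trend_fit()
  expect_warning(ec <- effect_curve(fit_t, "year", grid = 2008:2022),
                 "extrapolat")
  expect_equal(nrow(ec), 15L)
})
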