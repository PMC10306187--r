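test_that("an intercept-only fit yields a flat effect curve at the intercept", {
  set.seed(30)
  tab <- small_event_sim()$table[1:200, ]
  d <- assemble_design(tab, list(), tab$gpp)
  pls <- fit_penalized(d, numeric(0))
  fit <- cropgam:::finalize_fit(d, pls, list(score = NA, criterion = "REML"),
                                0, tab, model_config(), "trend", "gpp")
  ec <- effect_curve(fit, "year", grid = unique(tab$year))
  expect_true(all(ec$estimate == mean(tab$gpp)))
  expect_true(all(abs(ec$se - sqrt(fit$Vp[1, 1])) < 1e-12))
})

test_that("the seasonal effect curve recovers the injected curve shape", {
  sim <- small_trend_sim()
  fit <- small_trend_fit()
  ec <- effect_curve(fit, "month", grid = 1:12)
  expect_gt(cor(ec$estimate, sim$truth$seasonal$value), 0.99)
  expect_true(all(ec$se > 0))
  expect_true(!is.unsorted(ec$month))
})

test_that("pre/post month curves separate where a shift is injected and agree where none is", {
  cfg_shift <- small_event_config(seed = 301, post_phase_shift = 1.5)
  sim_s <- simulate_gpp(cfg_shift)
  fit_s <- fit_event_model(sim_s$table, small_model_config())
  pre_s <- effect_curve(fit_s, "month", grid = 1:12, level = "pre")
  post_s <- effect_curve(fit_s, "month", grid = 1:12, level = "post")
  cf <- cfg_shift
  true_diff <- cropgam:::seasonal_curve(1:12 + cf$post_phase_shift,
                                        cf$seasonal_amp, cf$seasonal_phase) -
    cropgam:::seasonal_curve(1:12, cf$seasonal_amp, cf$seasonal_phase) +
    cf$delta
  sep <- abs(post_s$estimate - pre_s$estimate)
  big <- which(abs(true_diff) > 1)  # months with strong injected divergence
  expect_true(all(sep[big] > 2 * pmax(pre_s$se[big], post_s$se[big])))
  # no injected seasonal change (delta only): curves coincide within 2 SE
  # after removing the step
  fit_0 <- small_event_fit()
  pre_0 <- effect_curve(fit_0, "month", grid = 1:12, level = "pre")
  post_0 <- effect_curve(fit_0, "month", grid = 1:12, level = "post")
  step <- event_effect_test(fit_0)$estimate
  gap <- abs(post_0$estimate - step - pre_0$estimate)
  expect_true(all(gap < 2 * (pre_0$se + post_0$se)))
})

test_that("surfaces are flat for constant spatial truth and peak at injected bumps", {
  cfg_flat <- trend_sim_config(seed = 311, trend_slope = 0)
  cfg_flat$bumps <- NULL
  sim_f <- simulate_gpp(cfg_flat)
  fit_f <- fit_trend_model(sim_f$table, model_config(space_k = 30))
  sf <- predict_surface(fit_f, classify = FALSE)
  inh <- sf[sf$in_hull, ]
  expect_true(all(abs(inh$estimate - mean(inh$estimate)) < 2 * inh$se))
  # two-bump field: fitted maxima within one pixel of the true centers
  sim_b <- small_trend_sim()
  fit_b <- small_trend_fit()
  px <- sim_b$truth$pixels
  sf_b <- predict_surface(fit_b, lon_grid = sort(unique(px$longitude)),
                          lat_grid = sort(unique(px$latitude)),
                          classify = FALSE)
  cell <- c(diff(sort(unique(px$longitude)))[1],
            diff(sort(unique(px$latitude)))[1])
  bumps <- trend_sim_config()$bumps
  top <- sf_b[which.max(sf_b$estimate), ]
  expect_lt(abs(top$longitude - bumps$lon[1]), 1.5 * cell[1])
  expect_lt(abs(top$latitude - bumps$lat[1]), 1.5 * cell[2])
  far <- sf_b[abs(sf_b$longitude - bumps$lon[1]) > 1 |
                abs(sf_b$latitude - bumps$lat[1]) > 1, ]
  top2 <- far[which.max(far$estimate), ]
  expect_lt(abs(top2$longitude - bumps$lon[2]), 1.5 * cell[1])
  expect_lt(abs(top2$latitude - bumps$lat[2]), 1.5 * cell[2])
})

test_that("post-period surface uncertainty exceeds pre-period uncertainty", {
  fit <- small_event_fit()
  pre <- predict_surface(fit, level = "pre", classify = FALSE)
  post <- predict_surface(fit, level = "post", classify = FALSE)
  # the post window is much shorter, so its level-specific smooths are
  # estimated from fewer composites
  expect_gt(median(post$se[post$in_hull]), median(pre$se[pre$in_hull]))
})

test_that("the step-change Wald test follows its arithmetic definition", {
  fake <- structure(list(coefficients = c(`(Intercept)` = 2, warpost = -0.30),
                         Ve = diag(c(0.1, 0.05^2)), factor_col = 2L,
                         df_residual = 500), class = "cropgam_fit")
  tt <- event_effect_test(fake)
  expect_equal(tt$t, -6)
  expect_equal(tt$p, 2 * stats::pt(-6, 500), tolerance = 1e-12)
  fake$coefficients[2] <- 0
  expect_equal(event_effect_test(fake)$p, 1)
  fit_trend <- small_trend_fit()
  expect_error(event_effect_test(fit_trend), "no event factor")
})

test_that("null-simulation p-values are approximately uniform", {
  # no injected step: the test statistic's p should be U(0,1) across
  # replicates (checked loosely by Kolmogorov-Smirnov)
  base_fit <- small_event_fit()
  cfg <- small_model_config(lambda_start = base_fit$lambda)
  ps <- vapply(1:60, function(i) {
    sim <- simulate_gpp(small_event_config(seed = 4000 + i, delta = 0))
    event_effect_test(fit_event_model(sim$table, cfg))$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("bivariate terciles classify a rank lattice, ties, and random data sensibly", {
  # 3 x 3 rank lattice: every class appears exactly once
  est <- rep(c(1, 2, 3), times = 3)
  se <- rep(c(0.1, 0.2, 0.3), each = 3)
  bt <- bivariate_terciles(est, se)
  expect_setequal(bt$class, 1:9)
  expect_length(unique(bt$hex), 9L)
  # all-equal estimates collapse to the lowest estimate tercile
  bt2 <- bivariate_terciles(rep(5, 9), se)
  expect_true(all(bt2$class %in% c(1, 4, 7)))
  # independent continuous data: each class frequency near 1/9
  set.seed(31)
  bt3 <- bivariate_terciles(rnorm(900), rexp(900))
  freq <- tabulate(bt3$class, 9) / 900
  expect_true(all(freq >= 0.06 & freq <= 0.17))
})
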