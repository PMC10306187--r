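test_that("cardinal CRS basis is the identity at its own knots and penalizes no line", {
  set.seed(1)
  x <- runif(200, 0, 10)
  b <- crs_basis(x, k = 7, constrain = FALSE, var = "x")
  kn <- b$meta$knots
  expect_equal(b$eval(data.frame(x = kn)), diag(7), tolerance = 1e-12)
  # coefficients of a straight line (= its values at the knots) have zero
  # roughness under the squared-second-derivative penalty
  beta_line <- 2 + 3 * kn
  expect_lt(abs(drop(t(beta_line) %*% b$pen[[1]] %*% beta_line)), 1e-10)
  # linear extrapolation beyond the knots
  X_out <- b$eval(data.frame(x = c(-1, 11)))
  f_out <- X_out %*% beta_line
  expect_equal(drop(f_out), 2 + 3 * c(-1, 11), tolerance = 1e-8)
  expect_error(crs_basis(c(1, 2, 3), k = 5), "distinct")
})

test_that("every penalty matrix is symmetric positive semi-definite", {
  set.seed(2)
  x <- runif(300, 0, 10); m <- sample(1:12, 300, TRUE)
  lon <- runif(300, 30, 33); lat <- runif(300, 46, 49)
  blocks <- list(
    crs_basis(x, k = 8, var = "x"),
    cyclic_basis(m, k = 12),
    gp_basis(lon, lat, k = 25),
    tensor_interaction(crs_basis(x, k = 5, var = "x"), cyclic_basis(m, k = 6)))
  for (b in blocks) {
    for (S in b$pen) {
      expect_equal(S, t(S), tolerance = 1e-10)
      ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
      expect_gt(min(ev), -1e-8 * max(ev))
    }
  }
})

test_that("constrained smooth contributions sum to zero over the data", {
  set.seed(3)
  x <- runif(400, 0, 10); m <- sample(1:12, 400, TRUE)
  lon <- runif(400, 30, 33); lat <- runif(400, 46, 49)
  blocks <- list(crs_basis(x, k = 8, var = "x"),
                 cyclic_basis(m, k = 12),
                 gp_basis(lon, lat, k = 20))
  for (b in blocks) {
    expect_lt(max(abs(colSums(b$X))), 1e-8)
    for (i in 1:5) {                     # random coefficient vectors
      beta <- rnorm(ncol(b$X))
      expect_lt(abs(sum(b$X %*% beta)), 1e-6 * nrow(b$X) * sd(b$X %*% beta))
    }
  }
})

test_that("cyclic basis is exactly periodic so the fitted season is continuous at the wrap", {
  m <- rep(1:12, 10)
  cb <- cyclic_basis(m, k = 12, constrain = FALSE, var = "m")
  grid <- seq(0.5, 1.5, by = 0.05)
  rows_a <- cb$eval(data.frame(m = grid))
  rows_b <- cb$eval(data.frame(m = grid + 12))
  expect_lt(max(abs(rows_a - rows_b)), 1e-10)
  # fitted smooth on sin data: value agrees across the wrap to 1e-8
  set.seed(4)
  mm <- runif(500, 1, 13)
  y <- sin(2 * pi * mm / 12) + rnorm(500, 0, 0.05)
  tab <- tibble::tibble(m = mm)
  blk <- cyclic_basis(mm, k = 12, origin = 1, var = "m")
  d <- assemble_design(tab, list(blk), y)
  f <- fit_penalized(d, 1)
  eps <- 1e-6
  f_lo <- drop(cbind(1, blk$eval(data.frame(m = 1 + eps))) %*% f$coefficients)
  f_hi <- drop(cbind(1, blk$eval(data.frame(m = 13 + eps))) %*% f$coefficients)
  expect_lt(abs(f_lo - f_hi), 1e-8)
})

test_that("cyclic basis dimension cannot exceed the distinct values", {
  expect_error(cyclic_basis(rep(1:6, 4), k = 12), "distinct")
})

test_that("Nystrom GP basis reconstructs the full kernel and improves with rank", {
  set.seed(5)
  n <- 500
  lon <- runif(n, 30, 33); lat <- runif(n, 46, 49)
  # brute-force full kernel as the oracle
  D <- outer(seq_len(n), seq_len(n),
             function(i, j) haversine_km(lon[i], lat[i], lon[j], lat[j]))
  rng <- max(D) / 2
  K <- matern32(D, rng)
  rel_err <- function(k) {
    g <- gp_basis(lon, lat, k = k, range = rng, constrain = FALSE)
    Khat <- g$X %*% diag(g$meta$eigenvalues) %*% t(g$X)
    norm(K - Khat, "F") / norm(K, "F")
  }
  errs <- vapply(c(10, 25, 50), rel_err, numeric(1))
  expect_lt(errs[3], 0.2)
  expect_true(all(diff(errs) < 0))         # monotone improvement in k
  expect_equal(matern32(0, 123), 1)
  expect_error(gp_basis(lon[1:10], lat[1:10], k = 50), "n = 10 < k")
})

test_that("tensor products have Kronecker dimensions and margin-wise penalties", {
  set.seed(6)
  x <- runif(200, 0, 10); m <- sample(1:12, 200, TRUE)
  a <- crs_basis(x, k = 4, constrain = FALSE, var = "x")
  b <- cyclic_basis(m, k = 3, constrain = FALSE, var = "m")
  tp <- tensor_interaction(a, b)
  expect_equal(ncol(tp$X), 12L)
  expect_length(tp$pen, 2L)
  # oracle: explicit Kronecker quadratic forms; a coefficient vector flat in
  # margin a is unpenalized by margin a and carries p_a copies of the pure-b
  # roughness
  bv <- rnorm(3)
  beta <- rep(1, 4) %x% bv
  qa <- drop(t(beta) %*% tp$pen[[1]] %*% beta)
  qb <- drop(t(beta) %*% tp$pen[[2]] %*% beta)
  expect_lt(abs(qa), 1e-8)
  expect_equal(qb, 4 * drop(t(bv) %*% b$pen[[1]] %*% bv), tolerance = 1e-10)
  # constant margin reproduces the other block's columns
  const <- cropgam:::new_basis_block(matrix(1, 200, 1), list(matrix(0, 1, 1)),
                                     "const", "c", function(nd) matrix(1, nrow(nd), 1))
  expect_equal(tensor_interaction(const, b)$X, b$X)
  expect_error(tensor_interaction(a, cyclic_basis(m[1:50], k = 3, var = "m")),
               "row counts")
})

test_that("by-factor copies zero the other level's rows and keep penalties", {
  set.seed(7)
  m <- sample(1:12, 120, TRUE)
  f <- factor(rep(c("pre", "post"), each = 60), levels = c("pre", "post"))
  blk <- cyclic_basis(m, k = 6, var = "month")
  copies <- by_factor(blk, f)
  expect_length(copies, 2L)
  expect_true(all(copies[[1]]$X[f == "post", ] == 0))
  expect_true(all(copies[[2]]$X[f == "pre", ] == 0))
  # disjoint support makes the two copies column-orthogonal
  expect_equal(max(abs(crossprod(copies[[1]]$X, copies[[2]]$X))), 0)
  expect_identical(copies[[1]]$pen, blk$pen)
  # single-level factor warns and returns the block unchanged
  expect_warning(one <- by_factor(blk, factor(rep("pre", 120),
                                              levels = c("pre", "post"))),
                 "single-level")
  expect_identical(one[[1]]$X, blk$X)
})
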