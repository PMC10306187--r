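#' @title Smooth-term bases and penalties
#' @description
#' Construction of the design and penalty matrices for every smooth used by
#' the spatio-temporal model: cardinal cubic regression splines for the
#' inter-annual trend, cyclic cubic splines for the 12-month season, a
#' low-rank (Nystrom) Gaussian-process smooth for space, row-wise Kronecker
#' tensor products for interactions, and factor-specific ("by") copies for
#' the pre/post event model. Each builder returns a `basis_block`: the n x p
#' design evaluated at the data, a list of p x p penalty matrices, and an
#' evaluator closure that reproduces the (transformed) design at new data.
#' @name basis
NULL

new_basis_block <- function(X, pen, label, vars, evalfun, meta = list()) {
  structure(list(X = X, pen = pen, label = label, vars = vars,
                 eval = evalfun, meta = meta),
            class = "basis_block")
}

#' @export
print.basis_block <- function(x, ...) {
  cat(sprintf("basis_block '%s': %d x %d design, %d penalty matrix(es)\n",
              x$label, nrow(x$X), ncol(x$X), length(x$pen)))
  invisible(x)
}

# ---- cardinal cubic regression spline --------------------------------------

# Natural-cubic-spline value-to-curvature map. Knots xk (strictly increasing,
# length k): B (k-2 x k-2) and D (k-2 x k) such that the second derivatives at
# the interior knots are B^{-1} D beta for knot values beta; the roughness
# penalty integral of f''(x)^2 is then beta' D' B^{-1} D beta.
crs_setup <- function(xk) {
  k <- length(xk)
  if (k < 3) stop("need at least 3 knots for a cubic regression spline")
  h <- diff(xk)
  if (any(h <= 0)) stop("knots must be strictly increasing")
  B <- matrix(0, k - 2, k - 2)
  D <- matrix(0, k - 2, k)
  for (i in seq_len(k - 2)) {
    B[i, i] <- (h[i] + h[i + 1]) / 3
    if (i < k - 2) { B[i, i + 1] <- h[i + 1] / 6; B[i + 1, i] <- h[i + 1] / 6 }
    D[i, i] <- 1 / h[i]
    D[i, i + 1] <- -1 / h[i] - 1 / h[i + 1]
    D[i, i + 2] <- 1 / h[i + 1]
  }
  Fmat <- solve(B, D)                       # curvatures at interior knots
  Ffull <- rbind(0, Fmat, 0)                # natural end conditions
  S <- symz(crossprod(D, Fmat))             # integrated squared 2nd derivative
  list(knots = xk, h = h, Ffull = Ffull, S = S)
}

# Evaluate the cardinal basis (identity at the knots) at arbitrary x, with
# linear extension beyond the knot range.
crs_eval <- function(x, setup) {
  xk <- setup$knots; k <- length(xk); Ff <- setup$Ffull
  inside <- function(xv) {
    j <- findInterval(xv, xk, all.inside = TRUE)
    hj <- xk[j + 1] - xk[j]
    am <- (xk[j + 1] - xv) / hj
    ap <- (xv - xk[j]) / hj
    cm <- ((xk[j + 1] - xv)^3 / hj - hj * (xk[j + 1] - xv)) / 6
    cp <- ((xv - xk[j])^3 / hj - hj * (xv - xk[j])) / 6
    X <- matrix(0, length(xv), k)
    X[cbind(seq_along(xv), j)] <- am
    X[cbind(seq_along(xv), j + 1)] <- X[cbind(seq_along(xv), j + 1)] + ap
    X + cm * Ff[j, , drop = FALSE] + cp * Ff[j + 1, , drop = FALSE]
  }
  d_inside <- function(xv) {               # first derivative rows
    j <- findInterval(xv, xk, all.inside = TRUE)
    hj <- xk[j + 1] - xk[j]
    dam <- -1 / hj
    dap <- 1 / hj
    dcm <- -(3 * (xk[j + 1] - xv)^2 / hj - hj) / 6
    dcp <- (3 * (xv - xk[j])^2 / hj - hj) / 6
    X <- matrix(0, length(xv), k)
    X[cbind(seq_along(xv), j)] <- dam
    X[cbind(seq_along(xv), j + 1)] <- X[cbind(seq_along(xv), j + 1)] + dap
    X + dcm * Ff[j, , drop = FALSE] + dcp * Ff[j + 1, , drop = FALSE]
  }
  x <- as.numeric(x)
  out <- matrix(0, length(x), k)
  lo <- x < xk[1]; hi <- x > xk[k]; mid <- !lo & !hi
  if (any(mid)) out[mid, ] <- inside(x[mid])
  if (any(lo))                              # linear extension at each end
    out[lo, ] <- inside(rep(xk[1], sum(lo))) +
      (x[lo] - xk[1]) * d_inside(rep(xk[1], sum(lo)))
  if (any(hi))
    out[hi, ] <- inside(rep(xk[k], sum(hi))) +
      (x[hi] - xk[k]) * d_inside(rep(xk[k], sum(hi)))
  out
}

#' Cubic regression spline basis
#'
#' Cardinal natural-cubic-spline basis (the basis functions take value 1 at
#' one knot and 0 at the others) with the integrated-squared-second-derivative
#' penalty. Default knots are placed at quantiles of the unique covariate
#' values; the basis extends linearly beyond the knot range.
#'
#' @param x numeric covariate.
#' @param k basis dimension (number of knots), >= 3.
#' @param knots optional strictly increasing knot vector of length `k`.
#' @param constrain absorb the sum-to-zero identifiability constraint
#'   (default `TRUE`); with `FALSE` the raw cardinal basis is returned.
#' @param var covariate name used by the evaluator closure.
#' @return a `basis_block`.
#' @export
crs_basis <- function(x, k, knots = NULL, constrain = TRUE, var = "x") {
  ux <- sort(unique(as.numeric(x)))
  if (length(ux) < k)
    stop(sprintf("crs_basis: %d distinct values < basis dimension k = %d",
                 length(ux), k))
  if (is.null(knots)) {
    knots <- as.numeric(stats::quantile(ux, probs = seq(0, 1, length.out = k),
                                        type = 7, names = FALSE))
    knots <- unique(knots)
    if (length(knots) < k)
      stop("quantile knots are not distinct; supply `knots` explicitly")
  }
  if (length(knots) != k || is.unsorted(knots, strictly = TRUE))
    stop("`knots` must be strictly increasing and of length k")
  setup <- crs_setup(knots)
  evalfun <- function(newdata) crs_eval(newdata[[var]], setup)
  blk <- new_basis_block(
    X = crs_eval(x, setup), pen = list(setup$S),
    label = sprintf("s(%s)", var), vars = var, evalfun = evalfun,
    meta = list(kind = "crs", knots = knots, range = range(knots)))
  if (constrain) absorb_sumzero(blk) else blk
}

# ---- cyclic cubic regression spline ----------------------------------------

# Cyclic analogue: k basis functions on knots xk[1..k+1] with xk[k+1]
# identified with xk[1] (one period). Value, first and second derivatives
# match at the wrap point by construction.
cyclic_setup <- function(xk) {
  k <- length(xk) - 1
  if (k < 3) stop("need at least 4 knots (k >= 3) for a cyclic spline")
  h <- diff(xk)
  B <- matrix(0, k, k); D <- matrix(0, k, k)
  wrap <- function(i) ((i - 1) %% k) + 1
  for (i in seq_len(k)) {
    hm <- h[wrap(i - 1)]; hp <- h[i]
    B[i, i] <- (hm + hp) / 3
    B[i, wrap(i + 1)] <- B[i, wrap(i + 1)] + hp / 6
    B[i, wrap(i - 1)] <- B[i, wrap(i - 1)] + hm / 6
    D[i, i] <- -1 / hm - 1 / hp
    D[i, wrap(i + 1)] <- D[i, wrap(i + 1)] + 1 / hp
    D[i, wrap(i - 1)] <- D[i, wrap(i - 1)] + 1 / hm
  }
  Fmat <- solve(B, D)
  S <- symz(crossprod(D, Fmat))
  list(knots = xk, k = k, Fmat = Fmat, S = S)
}

cyclic_eval <- function(x, setup) {
  xk <- setup$knots; k <- setup$k; Fm <- setup$Fmat
  period <- xk[k + 1] - xk[1]
  xv <- xk[1] + (as.numeric(x) - xk[1]) %% period    # wrap into one period
  j <- findInterval(xv, xk, all.inside = TRUE)
  jn <- ifelse(j == k, 1L, j + 1L)                   # wrapped next knot index
  hj <- xk[j + 1] - xk[j]
  am <- (xk[j + 1] - xv) / hj
  ap <- (xv - xk[j]) / hj
  cm <- ((xk[j + 1] - xv)^3 / hj - hj * (xk[j + 1] - xv)) / 6
  cp <- ((xv - xk[j])^3 / hj - hj * (xv - xk[j])) / 6
  X <- matrix(0, length(xv), k)
  X[cbind(seq_along(xv), j)] <- am
  X[cbind(seq_along(xv), jn)] <- X[cbind(seq_along(xv), jn)] + ap
  X + cm * Fm[j, , drop = FALSE] + cp * Fm[jn, , drop = FALSE]
}

#' Cyclic cubic regression spline basis
#'
#' Cubic regression spline on a periodic covariate (months of the year):
#' value, slope and curvature match at the two ends of the period, and the
#' penalty is the cyclic analogue of the squared-second-derivative integral.
#' Default knots are evenly spaced over one period starting at the smallest
#' observed value (for months, `1, 2, ..., 13` with period 12).
#'
#' @param m numeric periodic covariate.
#' @param k basis dimension, >= 3; must not exceed the number of distinct
#'   values of `m`.
#' @param period the period length (12 for months).
#' @param origin left edge of the period (default `min(m)`).
#' @param constrain absorb the sum-to-zero constraint (default `TRUE`).
#' @param var covariate name used by the evaluator closure.
#' @return a `basis_block`.
#' @export
cyclic_basis <- function(m, k = 12, period = 12, origin = NULL,
                         constrain = TRUE, var = "month") {
  m <- as.numeric(m)
  if (k > length(unique(m)))
    stop(sprintf("cyclic_basis: k = %d exceeds %d distinct values",
                 k, length(unique(m))))
  if (period <= 0) stop("`period` must be positive")
  if (is.null(origin)) origin <- min(m)
  xk <- seq(origin, origin + period, length.out = k + 1)
  setup <- cyclic_setup(xk)
  evalfun <- function(newdata) cyclic_eval(newdata[[var]], setup)
  blk <- new_basis_block(
    X = cyclic_eval(m, setup), pen = list(setup$S),
    label = sprintf("s(%s, cyclic)", var), vars = var, evalfun = evalfun,
    meta = list(kind = "cyclic", knots = xk, period = period))
  if (constrain) absorb_sumzero(blk) else blk
}

# ---- low-rank Gaussian-process spatial smooth ------------------------------

#' Matern covariance with smoothness 3/2
#'
#' `(1 + sqrt(3) d / range) * exp(-sqrt(3) d / range)`; unit marginal
#' variance, so the kernel equals 1 at distance 0.
#'
#' @param d distances (same units as `range`).
#' @param range the range (length-scale) parameter, > 0.
#' @return kernel values in (0, 1].
#' @export
matern32 <- function(d, range) {
  if (range <= 0) stop("`range` must be positive")
  s <- sqrt(3) * d / range
  (1 + s) * exp(-s)
}

# greedy farthest-point design: deterministic knot selection over rows of a
# distance matrix; starts from the point closest to the medoid
farthest_points <- function(D, k) {
  n <- nrow(D)
  first <- which.min(rowSums(D))
  sel <- integer(k); sel[1] <- first
  mind <- D[, first]
  for (i in seq_len(k - 1)) {
    nxt <- which.max(mind)
    sel[i + 1] <- nxt
    mind <- pmin(mind, D[, nxt])
  }
  sel
}

#' Low-rank Gaussian-process spatial basis
#'
#' Approximates a Gaussian-process smooth over longitude/latitude with a
#' Nystrom construction: `k` knots are chosen by a greedy farthest-point
#' design over the observed pixel locations, the Matern(3/2) kernel is built
#' at the knots and eigen-decomposed, and the data are projected onto the
#' scaled knot eigenbasis. With features `Z = K_nk U L^{-1}` and penalty
#' `diag(1/L)` the penalized quadratic form approximates the GP prior
#' `f' K^{-1} f`.
#'
#' @param lon,lat coordinates (degrees).
#' @param k number of knots (basis dimension before truncation).
#' @param range kernel range; default half the maximum inter-point distance.
#' @param distance `"km"` (great-circle, default) or `"degrees"` (Euclidean
#'   in coordinate units, for strict emulation of unprojected fits).
#' @param rank optional truncation: keep only the `rank` leading eigenpairs
#'   (used to slim the spatial margin inside tensor products).
#' @param constrain absorb the sum-to-zero constraint (default `TRUE`).
#' @param vars names of the two coordinate columns for the evaluator.
#' @return a `basis_block`; `meta$knots` holds the knot coordinates and
#'   `meta$range` the kernel range used.
#' @export
gp_basis <- function(lon, lat, k = 50, range = NULL,
                     distance = c("km", "degrees"), rank = NULL,
                     constrain = TRUE, vars = c("longitude", "latitude")) {
  distance <- match.arg(distance)
  pts <- cbind(as.numeric(lon), as.numeric(lat))
  if (any(!is.finite(pts))) stop("coordinates must be finite")
  upts <- unique(pts)
  if (nrow(pts) < k)
    stop(sprintf("gp_basis: n = %d < k = %d", nrow(pts), k))
  if (nrow(upts) < k) k <- nrow(upts)
  dfun <- if (distance == "km") {
    function(a, b) outer(seq_len(nrow(a)), seq_len(nrow(b)),
                         function(i, j) haversine_km(a[i, 1], a[i, 2], b[j, 1], b[j, 2]))
  } else {
    function(a, b) outer(seq_len(nrow(a)), seq_len(nrow(b)),
                         function(i, j) sqrt((a[i, 1] - b[j, 1])^2 + (a[i, 2] - b[j, 2])^2))
  }
  Du <- dfun(upts, upts)
  if (is.null(range)) range <- max(Du) / 2
  if (range <= 0) stop("degenerate spatial configuration: zero range")
  sel <- farthest_points(Du, k)
  kn <- upts[sel, , drop = FALSE]
  if (anyDuplicated(kn)) {                       # jitter-and-retry once
    kn <- kn + stats::runif(length(kn), -1e-8, 1e-8)
    if (anyDuplicated(kn)) stop("duplicate spatial knots")
  }
  Kkk <- matern32(dfun(kn, kn), range)
  eg <- eigen(symz(Kkk), symmetric = TRUE)
  keep <- eg$values > 1e-10 * eg$values[1]
  if (!is.null(rank)) keep <- keep & (seq_along(eg$values) <= rank)
  U <- eg$vectors[, keep, drop = FALSE]
  lam <- eg$values[keep]
  proj <- U %*% diag(1 / lam, nrow = length(lam))  # K_nk %*% proj = features
  evalfun <- function(newdata) {
    nd <- cbind(as.numeric(newdata[[vars[1]]]), as.numeric(newdata[[vars[2]]]))
    matern32(dfun(nd, kn), range) %*% proj
  }
  X <- matern32(dfun(pts, kn), range) %*% proj
  blk <- new_basis_block(
    X = X, pen = list(diag(1 / lam, nrow = length(lam))),
    label = sprintf("s(%s,%s, gp)", vars[1], vars[2]), vars = vars,
    evalfun = evalfun,
    meta = list(kind = "gp", knots = kn, range = range, distance = distance,
                eigenvalues = lam))
  if (constrain) absorb_sumzero(blk) else blk
}

# ---- identifiability -------------------------------------------------------

#' Absorb the sum-to-zero identifiability constraint
#'
#' Reparameterizes a block so that every remaining design column sums to zero
#' over the data (the fitted contribution of the smooth then averages to zero,
#' leaving the level to the intercept). The constraint null space is obtained
#' from the QR decomposition of the column-sum vector; penalties and the
#' evaluator closure are transformed consistently.
#'
#' @param block a `basis_block`.
#' @param rows optional row subset over which the column sums are taken
#'   (used for factor-level copies, which are centered over their own rows).
#' @return the constrained `basis_block` (one column fewer).
#' @export
absorb_sumzero <- function(block, rows = NULL) {
  X <- block$X
  cs <- if (is.null(rows)) colSums(X) else colSums(X[rows, , drop = FALSE])
  if (sqrt(sum(cs^2)) < 1e-12 * max(1, sqrt(nrow(X))))
    return(block)                                   # already centered
  qr_c <- qr(matrix(cs, ncol = 1))
  Q <- qr.Q(qr_c, complete = TRUE)
  Z <- Q[, -1, drop = FALSE]
  prev_eval <- block$eval
  prev_T <- block$meta$transform
  block$X <- X %*% Z
  block$pen <- lapply(block$pen, function(S) symz(crossprod(Z, S %*% Z)))
  block$eval <- function(newdata) prev_eval(newdata) %*% Z
  block$meta$transform <- if (is.null(prev_T)) Z else prev_T %*% Z
  block$meta$constrained <- TRUE
  block
}

# ---- tensor products and by-factor smooths ---------------------------------

#' Tensor-product interaction of two basis blocks
#'
#' Row-wise Kronecker product of two marginal designs, with one penalty per
#' margin (`S_a (x) I` and `I (x) S_b`), so each margin keeps its own
#' smoothing parameter. Build it from *constrained* margins to obtain an
#' interaction-only smooth that is identifiable alongside the main effects.
#'
#' @param a,b `basis_block`s on the same data rows.
#' @return a `basis_block` with two penalties.
#' @export
tensor_interaction <- function(a, b) {
  if (nrow(a$X) != nrow(b$X)) stop("tensor margins have different row counts")
  pa <- ncol(a$X); pb <- ncol(b$X)
  X <- row_kron(a$X, b$X)
  Ia <- diag(pa); Ib <- diag(pb)
  pen <- c(lapply(a$pen, function(S) S %x% Ib),
           lapply(b$pen, function(S) Ia %x% S))
  ea <- a$eval; eb <- b$eval
  new_basis_block(
    X = X, pen = pen,
    label = sprintf("ti(%s,%s)", paste(a$vars, collapse = ","),
                    paste(b$vars, collapse = ",")),
    vars = unique(c(a$vars, b$vars)),
    evalfun = function(newdata) row_kron(ea(newdata), eb(newdata)),
    meta = list(kind = "tensor", margins = c(a$label, b$label),
                margin_dims = c(pa, pb)))
}

#' Factor-specific ("by") copies of a smooth
#'
#' Produces one copy of the block per factor level, with design rows zeroed
#' outside that level, giving level-specific smooth curves/surfaces (the
#' pre/post event model). Penalties are carried over unchanged per copy (each
#' copy gets its own smoothing parameter(s)).
#'
#' Build the block *constrained* (centered over all rows, the default of the
#' basis constructors) before copying: with constants excluded from every
#' copy's span, the factor's own dummy stays identifiable, while each level's
#' smooth remains free to carry the correct seasonal/spatial mean of its own
#' observation window — which is what lets the factor coefficient estimate a
#' pure step change rather than absorbing composition differences between
#' the pre and post windows.
#'
#' @param block a `basis_block` (constrained; see Details).
#' @param f a factor of length `nrow(block$X)`.
#' @param fvar name of the factor column for the evaluator closure.
#' @return list of `basis_block`s, one per level, in level order.
#' @export
by_factor <- function(block, f, fvar = "war") {
  f <- as.factor(f)
  if (length(f) != nrow(block$X)) stop("factor length must match design rows")
  levs <- levels(droplevels(f))
  if (length(levs) < 2) {
    warning("by_factor: single-level factor; returning the block unchanged")
    return(list(block))
  }
  lapply(levs, function(lv) {
    ind <- as.numeric(f == lv)
    cp <- block
    cp$X <- block$X * ind
    prev_eval <- block$eval
    cp$eval <- function(newdata) {
      prev_eval(newdata) * as.numeric(as.character(newdata[[fvar]]) == lv)
    }
    cp$label <- sprintf("%s:%s%s", block$label, fvar, lv)
    cp$meta$by_level <- lv
    cp$meta$by_var <- fvar
    if (all(ind == 0))
      warning(sprintf("by_factor: level '%s' has no rows; degenerate zero design", lv))
    cp
  })
}
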