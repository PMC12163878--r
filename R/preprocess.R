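# Spectral preprocessing: SNV, MSC, Savitzky-Golay, airPLS, truncation,
# and ordered fit/apply pipelines with train-only statistics.

#' Standard normal variate
#'
#' Centers each spectrum (row) to mean zero and scales it to unit sample
#' standard deviation, removing affine scatter effects per spectrum.
#'
#' @param X Spectra matrix, rows = spectra.
#' @return Matrix of the same shape; every row has mean 0 and sample SD 1.
#' @export
snv <- function(X) {
  X <- as.matrix(X)
  s <- apply(X, 1, stats::sd)
  if (any(s == 0)) {
    bad <- rownames(X)[s == 0]
    if (is.null(bad)) bad <- which(s == 0)
    stop("constant spectrum (zero variance), cannot SNV: ", paste(bad, collapse = ", "))
  }
  (X - rowMeans(X)) / s
}

#' Multiplicative scatter correction
#'
#' Regresses each spectrum on a reference spectrum, `x ~ a * ref + b` by
#' ordinary least squares, and returns the de-scattered `(x - b) / a`. In
#' fit mode (no reference supplied) the reference is the column mean of `X`;
#' the reference used is returned so it can be reused unchanged on test
#' spectra.
#'
#' @param X Spectra matrix.
#' @param reference Reference spectrum, or `NULL` to use `colMeans(X)`.
#' @return List with `corrected` (matrix) and `reference` (vector).
#' @export
msc <- function(X, reference = NULL) {
  X <- as.matrix(X)
  if (is.null(reference)) reference <- colMeans(X)
  if (stats::sd(reference) == 0) stop("MSC reference has zero variance")
  rc <- reference - mean(reference)
  denom <- sum(rc^2)
  a <- drop(X %*% rc) / denom               # slope of OLS x ~ a*ref + b
  b <- rowMeans(X) - a * mean(reference)
  if (any(a == 0)) stop("MSC slope of zero; spectrum orthogonal to reference")
  corrected <- (X - b) / a
  list(corrected = corrected, reference = reference)
}

# Local polynomial fit coefficients: row vector c such that c %*% y gives the
# d-th derivative (w.r.t. the physical grid) at target offset 0.
.sg_coef <- function(offsets, polyorder, deriv) {
  A <- outer(offsets, 0:polyorder, `^`)
  # d-th derivative of the fitted polynomial at offset 0 is d! * beta_d
  e <- numeric(polyorder + 1); e[deriv + 1] <- factorial(deriv)
  drop(e %*% solve(crossprod(A), t(A)))
}

#' Savitzky-Golay smoothing and derivatives
#'
#' Replaces each point by the `deriv`-th derivative (with respect to
#' wavenumber, in cm-1) of the local least-squares polynomial of order
#' `polyorder` fitted over a sliding window. At the spectrum ends the
#' window is truncated and the polynomial refitted on the available points
#' rather than padding by reflection, so no data are fabricated at the
#' edges.
#'
#' @param X Spectra matrix (or a single spectrum as a vector).
#' @param window Odd window length (points).
#' @param polyorder Polynomial order, `< window`.
#' @param deriv Derivative order, `<= polyorder` (0 = smoothing).
#' @param step Grid step in cm-1 (positive); derivatives are per cm-1.
#' @param descending Is the grid descending (mid-IR convention)? Controls
#'   the sign of odd derivatives.
#' @return Matrix of the same shape as `X`.
#' @export
savgol <- function(X, window, polyorder, deriv = 0L, step = 1, descending = TRUE) {
  vec <- is.null(dim(X))
  X <- rbind(X)
  p <- ncol(X)
  if (window %% 2 != 1) stop("window must be odd")
  if (polyorder >= window) stop("polyorder must be < window")
  if (deriv > polyorder) stop("deriv must be <= polyorder")
  if (window > p) stop("window longer than spectrum")
  h <- (window - 1) / 2
  # physical offset of neighbour j-i is (grid[j]-grid[i]) = -step*(j-i) on a
  # descending grid, +step*(j-i) on an ascending one
  sgn <- if (descending) -1 else 1
  out <- matrix(NA_real_, nrow(X), p)
  interior <- .sg_coef(sgn * step * (-h:h), polyorder, deriv)
  idx <- (h + 1):(p - h)
  # interior: one shared coefficient vector, applied as a convolution
  for (i in idx) out[, i] <- X[, (i - h):(i + h), drop = FALSE] %*% interior
  # edges: truncated window, polynomial refit on available points
  for (i in seq_len(h)) {
    lo <- 1:min(window, p)
    cl <- .sg_coef(sgn * step * (lo - i), polyorder, deriv)
    out[, i] <- X[, lo, drop = FALSE] %*% cl
    j <- p - i + 1
    hi <- max(1, p - window + 1):p
    ch <- .sg_coef(sgn * step * (hi - j), polyorder, deriv)
    out[, j] <- X[, hi, drop = FALSE] %*% ch
  }
  if (vec) drop(out) else out
}

#' airPLS baseline correction
#'
#' Adaptive iteratively reweighted penalized least squares. The baseline
#' `z` minimizes `sum(w * (x - z)^2) + lambda * ||D2 z||^2` where `D2` is
#' the second difference operator; at each iteration points above the
#' current baseline (peaks) get weight zero and points below it get
#' exponentially increasing weight `exp(iter * |d_i| / |d|_1)` computed on
#' the negative residuals, until the L1 norm of the negative residuals
#' drops below `tol` times `|x|_1` or `max_iter` is reached.
#'
#' @param x Numeric spectrum (finite).
#' @param lambda Smoothness penalty, > 0. The default suits a ~900-point
#'   mid-IR grid.
#' @param max_iter Maximum reweighting iterations.
#' @param tol Convergence tolerance as a fraction of `sum(abs(x))`.
#' @return List with `baseline` and `corrected = x - baseline`.
#' @export
airpls <- function(x, lambda = 1e4, max_iter = 50L, tol = 1e-3) {
  if (!all(is.finite(x))) stop("x must be finite")
  if (lambda <= 0) stop("lambda must be > 0")
  m <- length(x)
  D <- Matrix::bandSparse(m - 2, m, k = 0:2,
                          diagonals = list(rep(1, m - 2), rep(-2, m - 2), rep(1, m - 2)))
  P <- lambda * Matrix::crossprod(D)
  w <- rep(1, m)
  z <- x
  for (it in seq_len(max_iter)) {
    W <- Matrix::Diagonal(m, w)
    z <- as.numeric(Matrix::solve(W + P, w * x))
    d <- x - z
    neg <- d < 0
    dssn <- sum(abs(d[neg]))
    if (dssn < tol * sum(abs(x))) break
    w[!neg] <- 0
    w[neg] <- exp(it * abs(d[neg]) / dssn)
    # anchor the ends so the baseline stays identifiable
    w[1] <- w[m] <- max(w)
  }
  list(baseline = z, corrected = x - z)
}

# Row-wise airPLS over a spectra matrix.
airpls_matrix <- function(X, lambda = 1e4, max_iter = 50L, tol = 1e-3) {
  t(apply(as.matrix(X), 1, function(r) airpls(r, lambda, max_iter, tol)$corrected))
}

#' Truncate spectra to a wavenumber interval
#'
#' @param X Spectra matrix.
#' @param grid Descending wavenumber vector matching `ncol(X)`.
#' @param low,high Interval bounds in cm-1, `low < high`, inside the grid span.
#' @return List with `X` (kept columns) and `grid` (still descending).
#' @export
truncate_spectra <- function(X, grid, low, high) {
  X <- rbind(X)
  if (low >= high) stop("low must be < high")
  keep <- grid >= low & grid <= high
  if (!any(keep)) stop("truncation interval selects no wavenumbers")
  list(X = X[, keep, drop = FALSE], grid = grid[keep])
}

#' Build a preprocessing step
#'
#' @param kind One of "snv", "msc", "savgol", "airpls", "truncate",
#'   "mean_center".
#' @param ... Step parameters: `savgol` takes `window`, `polyorder`,
#'   `deriv`; `airpls` takes `lambda`, `max_iter`, `tol`; `truncate` takes
#'   `low`, `high`.
#' @return A `pp_step` object.
#' @export
pp_step <- function(kind = c("snv", "msc", "savgol", "airpls", "truncate", "mean_center"), ...) {
  kind <- match.arg(kind)
  params <- list(...)
  if (kind == "savgol") {
    stopifnot(!is.null(params$window), !is.null(params$polyorder))
    if (params$window %% 2 != 1) stop("savgol window must be odd")
    if (params$polyorder >= params$window) stop("savgol polyorder must be < window")
    if (is.null(params$deriv)) params$deriv <- 0L
    if (params$deriv > params$polyorder) stop("savgol deriv must be <= polyorder")
  }
  if (kind == "airpls") {
    if (is.null(params$lambda)) params$lambda <- 1e4
    if (params$lambda <= 0) stop("airpls lambda must be > 0")
    if (is.null(params$max_iter)) params$max_iter <- 50L
    if (is.null(params$tol)) params$tol <- 1e-3
  }
  if (kind == "truncate") stopifnot(!is.null(params$low), !is.null(params$high))
  structure(list(kind = kind, params = params), class = "pp_step")
}

#' Build a preprocessing pipeline
#'
#' An ordered list of steps; statistics that depend on the data (the MSC
#' reference, the mean-centering vector) are estimated on training spectra
#' by [fit_pipeline()] and reused unchanged on test spectra by
#' [apply_pipeline()].
#'
#' @param ... `pp_step` objects, applied in order.
#' @return A `pp_pipeline` object (unfitted).
#' @export
pp_pipeline <- function(...) {
  steps <- list(...)
  if (length(steps) == 1 && is.list(steps[[1]]) && !inherits(steps[[1]], "pp_step"))
    steps <- steps[[1]]
  stopifnot(all(vapply(steps, inherits, logical(1), "pp_step")))
  structure(list(steps = steps, fitted = FALSE, state = list()), class = "pp_pipeline")
}

#' Fit a pipeline on training spectra
#'
#' @param pipeline A `pp_pipeline`.
#' @param X Training spectra matrix.
#' @param grid Wavenumber grid for `X` (descending).
#' @return List with `pipeline` (fitted), `X` (transformed training
#'   spectra) and `grid` (grid after any truncation).
#' @export
fit_pipeline <- function(pipeline, X, grid) {
  X <- as.matrix(X)
  state <- list()
  for (i in seq_along(pipeline$steps)) {
    st <- pipeline$steps[[i]]
    res <- switch(st$kind,
      snv = list(X = snv(X), grid = grid),
      msc = {
        m <- msc(X)                      # reference = training mean
        state[[as.character(i)]] <- list(reference = m$reference)
        list(X = m$corrected, grid = grid)
      },
      savgol = list(
        X = savgol(X, st$params$window, st$params$polyorder, st$params$deriv,
                   step = abs(grid[1] - grid[2])),
        grid = grid),
      airpls = list(X = airpls_matrix(X, st$params$lambda, st$params$max_iter, st$params$tol),
                    grid = grid),
      truncate = {
        tr <- truncate_spectra(X, grid, st$params$low, st$params$high)
        list(X = tr$X, grid = tr$grid)
      },
      mean_center = {
        mu <- colMeans(X)
        state[[as.character(i)]] <- list(center = mu)
        list(X = sweep(X, 2, mu), grid = grid)
      }
    )
    X <- res$X; grid <- res$grid
  }
  pipeline$fitted <- TRUE
  pipeline$state <- state
  pipeline$out_grid <- grid
  list(pipeline = pipeline, X = X, grid = grid)
}

#' Apply a fitted pipeline to new spectra
#'
#' Uses the training statistics frozen at fit time (MSC reference, centering
#' vector, truncation window); never re-estimates anything from `X`.
#'
#' @param pipeline A fitted `pp_pipeline`.
#' @param X New spectra matrix on the same input grid the pipeline was
#'   fitted on.
#' @param grid Wavenumber grid for `X`.
#' @return List with `X` (transformed) and `grid`.
#' @export
apply_pipeline <- function(pipeline, X, grid) {
  if (!isTRUE(pipeline$fitted)) stop("pipeline must be fitted before applying to new spectra")
  X <- as.matrix(X)
  for (i in seq_along(pipeline$steps)) {
    st <- pipeline$steps[[i]]
    res <- switch(st$kind,
      snv = list(X = snv(X), grid = grid),
      msc = list(X = msc(X, reference = pipeline$state[[as.character(i)]]$reference)$corrected,
                 grid = grid),
      savgol = list(
        X = savgol(X, st$params$window, st$params$polyorder, st$params$deriv,
                   step = abs(grid[1] - grid[2])),
        grid = grid),
      airpls = list(X = airpls_matrix(X, st$params$lambda, st$params$max_iter, st$params$tol),
                    grid = grid),
      truncate = {
        tr <- truncate_spectra(X, grid, st$params$low, st$params$high)
        list(X = tr$X, grid = tr$grid)
      },
      mean_center = list(X = sweep(X, 2, pipeline$state[[as.character(i)]]$center), grid = grid)
    )
    X <- res$X; grid <- res$grid
  }
  list(X = X, grid = grid)
}

#' Fit a pipeline on training spectra and apply it to test spectra
#'
#' @param pipeline A `pp_pipeline`.
#' @param X_train,X_test Spectra matrices on a shared grid.
#' @param grid Wavenumber grid (descending).
#' @return List with `X_train`, `X_test`, `grid` (post-truncation) and the
#'   fitted `pipeline`.
#' @export
fit_apply_pipeline <- function(pipeline, X_train, X_test, grid) {
  ft <- fit_pipeline(pipeline, X_train, grid)
  ap <- apply_pipeline(ft$pipeline, X_test, grid)
  list(X_train = ft$X, X_test = ap$X, grid = ft$grid, pipeline = ft$pipeline)
}
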