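test_that("snv normalizes rows exactly and is idempotent", {
  expect_equal(drop(snv(rbind(c(1, 2, 3)))), c(-1, 0, 1))
  set.seed(1)
  X <- matrix(rnorm(10 * 50), 10)
  Z <- snv(X)
  expect_true(all(abs(rowMeans(Z)) < 1e-12))
  expect_true(all(abs(apply(Z, 1, sd) - 1) < 1e-12))
  # affine invariance and idempotence
  expect_equal(snv(2.5 * X + 7), Z)
  expect_equal(snv(Z), Z)
  expect_error(snv(rbind(rep(2, 5), 1:5)), "constant spectrum")
})

test_that("msc inverts affine scatter and matches the least-squares oracle", {
  set.seed(2)
  ref <- cumsum(rnorm(30))
  a <- runif(6, 0.5, 2); b <- rnorm(6)
  X <- outer(a, ref) + b
  out <- msc(X, reference = ref)
  expect_equal(out$corrected, matrix(ref, 6, 30, byrow = TRUE), tolerance = 1e-10)
  # single row equal to the reference passes through unchanged
  expect_equal(drop(msc(rbind(ref), reference = ref)$corrected), ref)
  # fitted (a, b) match per-row OLS of spectrum on reference
  Y <- matrix(rnorm(5 * 20), 5)
  r2 <- colMeans(Y)
  got <- msc(Y, reference = r2)$corrected
  oracle <- t(apply(Y, 1, function(row) {
    co <- coef(lm(row ~ r2))
    (row - co[1]) / co[2]
  }))
  expect_equal(got, oracle, tolerance = 1e-10)
  expect_error(msc(Y, reference = rep(1, 20)), "zero variance")
})

test_that("savgol reproduces polynomials and matches a sliding-refit oracle", {
  p <- 41; step <- 4
  wn <- seq(4000, by = -step, length.out = p)   # descending grid
  quad <- 3 + 0.002 * wn + 1e-6 * wn^2
  sm <- savgol(quad, window = 7, polyorder = 2, deriv = 0, step = step)
  expect_equal(sm, quad, tolerance = 1e-10)
  # derivative of a linear ramp is its slope per cm-1, including at edges
  m <- 0.37
  lin <- 5 + m * wn
  d1 <- savgol(lin, window = 7, polyorder = 2, deriv = 1, step = step)
  expect_equal(d1, rep(m, p), tolerance = 1e-10)
  # second derivative of the quadratic
  d2 <- savgol(quad, window = 7, polyorder = 2, deriv = 2, step = step)
  expect_equal(d2, rep(2e-6, p), tolerance = 1e-10)
  # random row: explicit per-window polynomial refit oracle (interior)
  set.seed(3)
  x <- rnorm(p)
  got <- savgol(x, window = 5, polyorder = 2, deriv = 2, step = step)
  for (i in c(3, 10, 25, p - 2)) {
    idx <- (i - 2):(i + 2)
    fit <- lm(x[idx] ~ poly(wn[idx] - wn[i], 2, raw = TRUE))
    expect_equal(got[i], 2 * unname(coef(fit)[3]), tolerance = 1e-8)
  }
  # polyorder = window - 1, deriv 0 is the identity on interior points
  ident <- savgol(x, window = 5, polyorder = 4, deriv = 0, step = step)
  expect_equal(ident[3:(p - 2)], x[3:(p - 2)], tolerance = 1e-8)
  expect_error(savgol(x, window = 6, polyorder = 2), "odd")
  expect_error(savgol(x, window = 7, polyorder = 2, deriv = 3), "deriv")
})

test_that("savgol interior smoothing agrees with an independent implementation", {
  set.seed(4)
  x <- cumsum(rnorm(100))
  got <- savgol(x, window = 11, polyorder = 3, deriv = 0, step = 1)
  ref <- signal::sgolayfilt(x, p = 3, n = 11)
  expect_equal(got[6:95], ref[6:95], tolerance = 1e-10)
})

test_that("airpls tracks peak-free baselines and preserves peak heights", {
  wn <- seq_len(500)
  smooth <- 0.5 + 1e-3 * wn - 1e-6 * wn^2
  out <- airpls(smooth + rnorm(500, 0, 1e-5), lambda = 1e4)
  expect_lt(max(abs(out$corrected)), 0.05 * diff(range(smooth)))
  # flat baseline + one positive Gaussian peak
  peak <- 2 * exp(-0.5 * ((wn - 250) / 15)^2)
  out2 <- airpls(1 + peak, lambda = 1e5)
  expect_lt(abs(max(out2$corrected) - 2) / 2, 0.10)
  away <- abs(wn - 250) > 80
  expect_lt(max(abs(out2$baseline[away] - 1)), 0.10)
  # corrected spectrum invariant to adding a smooth baseline below the cutoff
  tilt <- 0.3 + 5e-4 * wn
  out3 <- airpls(1 + peak + tilt, lambda = 1e5)
  expect_equal(out3$corrected, out2$corrected, tolerance = 0.08)
  # penalty limit: curvature of the baseline decreases with lambda
  curv <- function(lam) sum(diff(airpls(1 + peak + tilt, lambda = lam)$baseline, differences = 2)^2)
  cs <- vapply(c(1e3, 1e5, 1e7), curv, numeric(1))
  expect_true(all(diff(cs) < 0))
  expect_error(airpls(c(1, NA, 2)), "finite")
  expect_error(airpls(smooth, lambda = -1), "lambda")
})

test_that("truncation selects the requested wavenumber window", {
  grid <- seq(4000, 400, by = -4)
  X <- matrix(rnorm(2 * length(grid)), 2)
  full <- truncate_spectra(X, grid, 400, 4000)
  expect_identical(full$X, X)
  fp <- truncate_spectra(X, grid, 900, 1800)
  expect_equal(ncol(fp$X), (1800 - 900) / 4 + 1)
  expect_true(all(diff(fp$grid) < 0))
  expect_error(truncate_spectra(X, grid, 4500, 5000), "no wavenumbers")
  expect_error(truncate_spectra(X, grid, 1800, 900), "low")
})

test_that("pipelines freeze training statistics and preserve step order", {
  set.seed(5)
  grid <- seq(2000, 1000, by = -4)
  Xtr <- matrix(rnorm(8 * length(grid), 1), 8)
  Xte <- matrix(rnorm(4 * length(grid), 5), 4)   # very different mean
  # empty pipeline is the identity
  out0 <- fit_apply_pipeline(pp_pipeline(list()), Xtr, Xte, grid)
  expect_identical(out0$X_train, Xtr)
  expect_identical(out0$X_test, Xte)
  # msc: test spectra corrected against the TRAINING mean, not their own
  out <- fit_apply_pipeline(pp_pipeline(pp_step("msc")), Xtr, Xte, grid)
  expect_equal(out$pipeline$state[["1"]]$reference, colMeans(Xtr))
  own_ref <- msc(Xte)$corrected
  expect_false(isTRUE(all.equal(out$X_test, own_ref)))
  expect_equal(out$X_test, msc(Xte, reference = colMeans(Xtr))$corrected)
  # truncate + savgol + snv: train and test emerge on the same grid
  pipe <- pp_pipeline(pp_step("truncate", low = 1200, high = 1800),
                      pp_step("savgol", window = 11, polyorder = 3, deriv = 1),
                      pp_step("snv"))
  out2 <- fit_apply_pipeline(pipe, Xtr, Xte, grid)
  expect_equal(ncol(out2$X_train), ncol(out2$X_test))
  expect_equal(out2$grid, grid[grid >= 1200 & grid <= 1800])
  # applying an unfitted pipeline is an error
  expect_error(apply_pipeline(pp_pipeline(pp_step("snv")), Xte, grid), "fitted")
})
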