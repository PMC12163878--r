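test_that("one latent variable captures exact one-factor structure", {
  set.seed(10)
  v <- rnorm(8); v <- v / sqrt(sum(v^2))
  t_true <- rnorm(30)
  X <- outer(t_true, v)                 # rank one, informative direction v
  y <- drop(X %*% v)
  fit <- fit_pls(X[1:20, ], y[1:20], n_lv = 1)
  expect_equal(drop(predict(fit, X[1:20, ])), y[1:20], tolerance = 1e-8)
  # held-out rows are exact too
  expect_equal(drop(predict(fit, X[21:30, ])), y[21:30], tolerance = 1e-8)
})

test_that("first NIPALS weight is the centered cross-covariance direction", {
  set.seed(11)
  X <- matrix(rnorm(20 * 6), 20)
  y <- rnorm(20)
  fit <- fit_pls(X, y, n_lv = 1)
  w_ref <- crossprod(scale(X, scale = FALSE), y - mean(y))
  w_ref <- drop(w_ref) / sqrt(sum(w_ref^2))
  cosine <- abs(sum(fit$W[, 1] * w_ref))
  expect_equal(cosine, 1, tolerance = 1e-10)
})

test_that("full-rank PLS equals ordinary least squares", {
  set.seed(12)
  for (rep in 1:5) {
    X <- matrix(rnorm(20 * 5), 20)
    y <- rnorm(20)
    fit <- fit_pls(X, y, n_lv = 5)
    Xc <- scale(X, scale = FALSE)
    beta <- qr.solve(Xc, y - mean(y))
    ols <- drop(Xc %*% beta) + mean(y)
    expect_equal(drop(predict(fit, X)), ols, tolerance = 1e-6)
  }
})

test_that("prediction identities hold", {
  set.seed(13)
  X <- matrix(rnorm(25 * 10), 25)
  Y <- cbind(rnorm(25), rnorm(25))
  fit <- fit_pls(X, Y, n_lv = 4)
  # training prediction equals T Q' + y_mean
  expect_equal(unname(predict(fit, X)),
               unname(fit$T %*% t(fit$Q) + rep(1, 25) %o% fit$y_mean),
               tolerance = 1e-8)
  # the training mean row predicts the response mean
  expect_equal(drop(predict(fit, rbind(fit$x_mean))), fit$y_mean, tolerance = 1e-12)
  # shifting an X column is absorbed by centering
  X2 <- X; X2[, 3] <- X2[, 3] + 100
  fit2 <- fit_pls(X2, Y, n_lv = 4)
  expect_equal(predict(fit2, X2), predict(fit, X), tolerance = 1e-6)
})

test_that("deflation leaves residuals orthogonal and fit improves monotonically", {
  set.seed(14)
  X <- matrix(rnorm(30 * 12), 30)
  y <- drop(X %*% rnorm(12)) + rnorm(30)
  A <- 6
  fit <- fit_pls(X, y, n_lv = A)
  # scores mutually orthogonal
  G <- crossprod(fit$T)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  # weights unit norm
  expect_equal(colSums(fit$W^2), rep(1, A), tolerance = 1e-12)
  # residual X orthogonal to all extracted scores
  Xc <- scale(X, scale = FALSE)
  E <- Xc - fit$T %*% t(fit$P)
  expect_lt(max(abs(crossprod(fit$T, E))), 1e-8)
  # training RMSE never increases with more components
  rmse_a <- vapply(1:A, function(a) sqrt(mean((y - predict(fit, X, n_lv = a))^2)), numeric(1))
  expect_true(all(diff(rmse_a) < 1e-10))
})

test_that("predictions agree with an independent PLS implementation", {
  suppressMessages(requireNamespace("mixOmics", quietly = TRUE))
  set.seed(15)
  for (rep in 1:25) {
    n <- sample(12:25, 1); p <- sample(4:10, 1)
    A <- sample(2:3, 1)
    X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("v", 1:p)))
    y <- drop(X %*% rnorm(p)) + rnorm(n)
    Xnew <- matrix(rnorm(5 * p), 5, dimnames = list(NULL, paste0("v", 1:p)))
    ours <- drop(predict(fit_pls(X, y, n_lv = A), Xnew))
    ref_fit <- mixOmics::pls(X, y, ncomp = A, mode = "regression", scale = FALSE)
    theirs <- drop(predict(ref_fit, Xnew)$predict[, 1, A])
    expect_equal(ours, unname(theirs), tolerance = 1e-6)
  }
})

test_that("VIP satisfies its identities and finds the informative variable", {
  set.seed(16)
  X <- matrix(rnorm(40 * 9), 40)
  y <- drop(X %*% rnorm(9))
  fit <- fit_pls(X, y, n_lv = 3)
  v <- vip(fit)
  expect_true(all(v >= 0))
  expect_equal(mean(v^2), 1, tolerance = 1e-8)
  # 1-LV collapse: VIP_j = sqrt(p) |w_j| / ||w||
  fit1 <- fit_pls(X, y, n_lv = 1)
  expect_equal(unname(vip(fit1)),
               sqrt(9) * abs(fit1$W[, 1]) / sqrt(sum(fit1$W[, 1]^2)),
               tolerance = 1e-10)
  # single informative variable is ranked first
  Xn <- matrix(rnorm(200 * 6), 200)
  yn <- 3 * Xn[, 3] + rnorm(200, 0, 0.1)
  expect_equal(unname(which.max(vip(fit_pls(Xn, yn, n_lv = 2)))), 3)
  expect_error(vip(list()), "pls_model")
})

test_that("serialized models reload and predict bit-compatibly", {
  set.seed(17)
  X <- matrix(rnorm(20 * 7), 20)
  Y <- cbind(a = rnorm(20), b = rnorm(20))
  fit <- fit_pls(X, Y, n_lv = 3)
  path <- tempfile(fileext = ".json")
  write_pls_model(fit, path)
  back <- read_pls_model(path)
  expect_equal(predict(back, X), predict(fit, X), tolerance = 1e-12)
  # PLS-DA wrapper round-trips too
  da <- fit_plsda(X, rep(c("u", "v"), 10), n_lv = 2)
  write_pls_model(da, path)
  da2 <- read_pls_model(path)
  expect_identical(predict(da2, X), predict(da, X))
})

test_that("degenerate fits are rejected", {
  X <- matrix(rnorm(10 * 4), 10)
  expect_error(fit_pls(X, rep(1, 10), n_lv = 1), "zero variance")
  expect_error(fit_pls(X, rnorm(10), n_lv = 12), "n_lv")
  expect_error(fit_pls(X[1, , drop = FALSE], 1, n_lv = 1), "2 samples")
})
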