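# NIPALS partial least squares (single and multi-response), regression
# coefficients, VIP scores, and JSON serialization.

#' Fit a PLS model by NIPALS
#'
#' Mean-centers `X` and `Y` and extracts `n_lv` latent variables by the
#' classical NIPALS sequence with deflation: for each component, iterate
#' weight -> score -> Y-loading until the score stabilizes, then deflate
#' both blocks by the extracted component. Regression coefficients for the
#' centered data are `B = W (P'W)^-1 Q'`. Component signs are fixed so the
#' largest-magnitude element of each weight vector is positive.
#'
#' @param X Predictor matrix (n x p), e.g. preprocessed spectra.
#' @param Y Response matrix (n x m) or vector; concentrations or dummy-coded
#'   classes. Centered only (no unit-variance scaling) unless
#'   `scale_y = TRUE`.
#' @param n_lv Number of latent variables, `1 <= n_lv <= min(n - 1, p)`.
#' @param scale_x,scale_y Optionally autoscale columns to unit variance
#'   before fitting (off by default; centering only).
#' @param tol Inner NIPALS convergence tolerance on the score vector.
#' @param max_inner Maximum inner iterations per component.
#' @return An object of class `pls_model` with fields `n_lv`, `x_mean`,
#'   `y_mean`, `W` (weights, unit-norm columns), `P` (X-loadings), `Q`
#'   (Y-loadings), `T` (training scores), `B` (p x m coefficients for
#'   centered data) and scaling vectors.
#' @export
fit_pls <- function(X, Y, n_lv, scale_x = FALSE, scale_y = FALSE,
                    tol = 1e-10, max_inner = 500L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)
  if (n < 2) stop("need at least 2 samples")
  if (nrow(Y) != n) stop("X and Y must be row-aligned")
  if (n_lv < 1 || n_lv > min(n - 1, p))
    stop(sprintf("n_lv must be in 1..min(n-1, p) = %d", min(n - 1, p)))
  if (all(apply(Y, 2, stats::sd) == 0)) stop("Y has zero variance")

  x_mean <- colMeans(X); y_mean <- colMeans(Y)
  x_scale <- if (scale_x) apply(X, 2, stats::sd) else rep(1, p)
  y_scale <- if (scale_y) apply(Y, 2, stats::sd) else rep(1, m)
  if (any(x_scale == 0) || any(y_scale == 0)) stop("cannot autoscale a constant column")
  E <- sweep(sweep(X, 2, x_mean), 2, x_scale, "/")
  F <- sweep(sweep(Y, 2, y_mean), 2, y_scale, "/")

  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv)
  Q <- matrix(0, m, n_lv); Tm <- matrix(0, n, n_lv)
  for (a in seq_len(n_lv)) {
    u <- F[, which.max(apply(F, 2, stats::var))]
    if (all(u == 0)) u <- F[, 1]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_inner)) {
      w <- drop(crossprod(E, u))
      nw <- sqrt(sum(w^2))
      if (nw == 0) stop("degenerate component: X residual orthogonal to Y residual")
      w <- w / nw
      t <- drop(E %*% w)
      q <- drop(crossprod(F, t)) / sum(t^2)
      if (m > 1) u <- drop(F %*% q) / sum(q^2) else u <- F[, 1]
      if (sqrt(sum((t - t_old)^2)) < tol * sqrt(sum(t^2))) break
      t_old <- t
    }
    # sign convention: largest-magnitude weight element positive
    s <- sign(w[which.max(abs(w))])
    w <- s * w; t <- s * t; q <- s * q
    pload <- drop(crossprod(E, t)) / sum(t^2)
    E <- E - tcrossprod(t, pload)
    F <- F - tcrossprod(t, q)
    W[, a] <- w; P[, a] <- pload; Q[, a] <- q; Tm[, a] <- t
  }
  B <- W %*% solve(crossprod(P, W), t(Q))
  structure(list(n_lv = n_lv, x_mean = x_mean, y_mean = y_mean,
                 x_scale = x_scale, y_scale = y_scale,
                 W = W, P = P, Q = Q, T = Tm, B = B,
                 x_names = colnames(X), y_names = colnames(Y)),
            class = "pls_model")
}

#' Predict responses from a fitted PLS model
#'
#' @param object A `pls_model`.
#' @param newdata Matrix on the model's grid/preprocessing (n x p).
#' @param n_lv Optionally predict with the first `n_lv` components only
#'   (defaults to the model's full count).
#' @param ... Unused.
#' @return Predicted response matrix (n x m), on the original Y scale.
#' @export
predict.pls_model <- function(object, newdata, n_lv = object$n_lv, ...) {
  newdata <- rbind(as.matrix(newdata))
  if (ncol(newdata) != length(object$x_mean))
    stop("newdata has ", ncol(newdata), " columns; model expects ", length(object$x_mean))
  if (n_lv < 1 || n_lv > object$n_lv) stop("n_lv out of range for this model")
  B <- if (n_lv == object$n_lv) object$B else {
    A <- seq_len(n_lv)
    object$W[, A, drop = FALSE] %*%
      solve(crossprod(object$P[, A, drop = FALSE], object$W[, A, drop = FALSE]),
            t(object$Q[, A, drop = FALSE]))
  }
  Xc <- sweep(sweep(newdata, 2, object$x_mean), 2, object$x_scale, "/")
  Yc <- Xc %*% B
  sweep(sweep(Yc, 2, object$y_scale, "*"), 2, object$y_mean, "+")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("pls_model: %d LV, %d predictors, %d response(s)\n",
              x$n_lv, nrow(x$W), nrow(x$Q)))
  invisible(x)
}

#' Variable importance in projection (VIP)
#'
#' `VIP_j = sqrt(p * sum_a SSY_a (w_ja / ||w_a||)^2 / sum_a SSY_a)` where
#' `SSY_a = q_a^2 t_a' t_a` is the Y sum of squares explained by component
#' `a`. Satisfies `mean(VIP^2) = 1` exactly.
#'
#' @param model A fitted `pls_model`.
#' @return Numeric vector of length p (one score per predictor), >= 0.
#' @export
vip <- function(model) {
  if (!inherits(model, "pls_model")) stop("model must be a fitted pls_model")
  p <- nrow(model$W)
  ssy <- colSums(model$Q^2) * colSums(model$T^2)   # q_a'q_a * t_a't_a
  Wn <- sweep(model$W, 2, sqrt(colSums(model$W^2)), "/")
  v <- sqrt(p * drop(Wn^2 %*% ssy) / sum(ssy))
  names(v) <- model$x_names
  v
}

#' Serialize a PLS model to JSON
#'
#' Writes every matrix and centering vector at full double precision so a
#' reloaded model reproduces predictions to machine accuracy.
#'
#' @param model A `pls_model` (or `plsda_model`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pls_model <- function(model, path) {
  obj <- unclass(model)
  obj$.class <- class(model)
  if (!is.null(obj$core)) {           # plsda_model embeds a pls_model
    obj$core <- unclass(obj$core)
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' Read back a serialized PLS model
#'
#' @param path File written by [write_pls_model()].
#' @return The restored model object.
#' @export
read_pls_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- obj$.class
  obj$.class <- NULL
  fix <- function(o) {
    for (f in c("W", "P", "Q", "T", "B")) o[[f]] <- as.matrix(o[[f]])
    o
  }
  if (!is.null(obj$core)) {
    obj$core <- structure(fix(obj$core), class = "pls_model")
  } else {
    obj <- fix(obj)
  }
  structure(obj, class = cls)
}
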