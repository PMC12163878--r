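# PLS regression of serum spectra onto tissue iron concentrations, with
# calibration/test figures of merit and pseudo-univariate LoD/LoQ.

rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))

r_squared <- function(obs, pred) 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)

#' Limits of detection and quantification of a calibration
#'
#' Pseudo-univariate convention: regress predicted on measured
#' concentration over the calibration samples; with `s` the residual
#' standard error of that line and `b` its slope, `LoD = 3.3 s / b` and
#' `LoQ = 10 s / b` (multipliers configurable).
#'
#' @param y_cal Measured calibration concentrations.
#' @param yhat_cal Model predictions for the calibration samples.
#' @param k_lod,k_loq Multipliers on `s / b`.
#' @return List with `lod`, `loq`, `slope`, `s`.
#' @export
lod_loq <- function(y_cal, yhat_cal, k_lod = 3.3, k_loq = 10) {
  fit <- stats::lm(yhat_cal ~ y_cal)
  b <- unname(stats::coef(fit)[2])
  if (!is.finite(b) || b <= 0) stop("calibration slope must be positive for LoD/LoQ")
  s <- sqrt(sum(stats::residuals(fit)^2) / stats::df.residual(fit))
  list(lod = k_lod * s / b, loq = k_loq * s / b, slope = b, s = s)
}

#' PLS regression of serum spectra on a tissue's iron concentration
#'
#' Selects the latent-variable count by class-stratified, animal-level
#' k-fold cross-validation on the calibration partition, fits the final
#' NIPALS model there, and reports the calibration and test figures of
#' merit: RMSEC / RMSEP, R2 of calibration and test, and pseudo-univariate
#' LoD / LoQ from the calibration fit.
#'
#' @param spectra A `spectra_set` (or preprocessed matrix via `X`).
#' @param tissue Which iron column of the metadata to predict
#'   ("blood", "spleen", "heart", "liver", "kidney").
#' @param plan A `split_plan` from [stratified_group_split()].
#' @param pipeline Preprocessing `pp_pipeline` (fitted on the calibration
#'   partition only).
#' @param max_lv Largest candidate component count.
#' @param k Cross-validation folds.
#' @param seed Seed for the fold plan.
#' @return List with `model` (`pls_model`), `metrics` (one-row data frame:
#'   tissue, n_lv, rmsec, rmsep, r2c, r2p, lod, loq), `predictions`
#'   (per-spectrum observed/predicted/partition).
#' @export
fit_tissue_regression <- function(spectra, tissue, plan, pipeline = NULL,
                                  max_lv = 15L, k = 5L, seed = 1L) {
  stopifnot(inherits(spectra, "spectra_set"))
  if (!tissue %in% names(spectra$meta)) stop("no iron column for tissue ", tissue)
  y <- spectra$meta[[tissue]]
  if (any(!is.finite(y)) || any(y <= 0)) stop("concentrations must be positive and finite")
  tr <- spectra$meta$animal_id %in% plan$train_ids
  te <- spectra$meta$animal_id %in% plan$test_ids
  Xtr <- spectra$absorbance[tr, , drop = FALSE]
  Xte <- spectra$absorbance[te, , drop = FALSE]
  grid <- spectra$wavenumbers
  fold_of <- kfold_plan(spectra$meta, plan$train_ids, k = k, seed = seed)
  folds <- fold_vector(fold_of, spectra$meta$animal_id[tr])
  sel <- select_lv(Xtr, y[tr], folds, max_lv = max_lv, objective = "rmse",
                   pipeline = pipeline, grid = grid)
  if (!is.null(pipeline)) {
    pp <- fit_apply_pipeline(pipeline, Xtr, Xte, grid)
    Xtr <- pp$X_train; Xte <- pp$X_test
  }
  model <- fit_pls(Xtr, y[tr], n_lv = sel$n_lv)
  yhat_c <- drop(predict(model, Xtr))
  yhat_p <- drop(predict(model, Xte))
  lim <- lod_loq(y[tr], yhat_c)
  metrics <- data.frame(tissue = tissue, n_lv = sel$n_lv,
                        rmsec = rmse(y[tr], yhat_c), rmsep = rmse(y[te], yhat_p),
                        r2c = r_squared(y[tr], yhat_c), r2p = r_squared(y[te], yhat_p),
                        lod = lim$lod, loq = lim$loq)
  predictions <- data.frame(
    spectrum_id = c(spectra$meta$spectrum_id[tr], spectra$meta$spectrum_id[te]),
    partition = rep(c("calibration", "test"), c(sum(tr), sum(te))),
    observed = c(y[tr], y[te]), predicted = c(yhat_c, yhat_p))
  list(model = model, metrics = metrics, predictions = predictions, cv = sel)
}
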