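# Replicate-aware partitioning and k-fold cross-validation for choosing
# the number of latent variables.

#' Stratified animal-level train/test split
#'
#' Splits at the animal level, independently within each dose class, so all
#' replicate spectra of an animal land in the same partition and each class
#' contributes close to `test_fraction` of its animals to the test set
#' (round-half-up on `n * test_fraction`). Deterministic given `seed`.
#'
#' @param meta Per-spectrum metadata with `animal_id` and `class` columns.
#' @param test_fraction Target proportion of animals per class in the test
#'   set (the study used 30 percent).
#' @param seed Integer seed.
#' @return A `split_plan`: list with `train_ids`, `test_ids` (animal ids)
#'   and the `test_fraction` and `seed` used.
#' @export
stratified_group_split <- function(meta, test_fraction = 0.30, seed = 1L) {
  stopifnot(all(c("animal_id", "class") %in% names(meta)))
  if (test_fraction <= 0 || test_fraction >= 1) stop("test_fraction must be in (0, 1)")
  animals <- unique(meta[, c("animal_id", "class")])
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  test_ids <- character(0)
  for (cl in sort(unique(as.character(animals$class)))) {
    ids <- sort(animals$animal_id[animals$class == cl])   # row-order invariant
    if (length(ids) < 2) stop("class ", cl, " has fewer than 2 animals; cannot split")
    n_test <- floor(length(ids) * test_fraction + 0.5)   # round half up
    n_test <- max(1L, min(n_test, length(ids) - 1L))
    test_ids <- c(test_ids, sample(ids, n_test))
  }
  structure(list(train_ids = setdiff(animals$animal_id, test_ids),
                 test_ids = test_ids,
                 test_fraction = test_fraction, seed = seed),
            class = "split_plan")
}

#' Class-stratified k-fold plan at animal level
#'
#' Assigns training animals to `k` folds, shuffled within class and dealt
#' round-robin so per-class fold sizes differ by at most one; replicates of
#' an animal never straddle folds because assignment is by animal.
#'
#' @param meta Per-spectrum metadata (`animal_id`, `class`).
#' @param train_ids Animal ids in the training partition.
#' @param k Number of folds (the study used 5).
#' @param seed Integer seed.
#' @return Named integer vector: fold index (1..k) per training animal id.
#' @export
kfold_plan <- function(meta, train_ids, k = 5L, seed = 1L) {
  if (k < 2) stop("k must be >= 2")
  animals <- unique(meta[, c("animal_id", "class")])
  animals <- animals[animals$animal_id %in% train_ids, ]
  if (nrow(animals) < k) stop("fewer training animals than folds")
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  fold_of <- integer(0)
  offset <- 0L
  for (cl in sort(unique(as.character(animals$class)))) {
    ids <- sample(sort(animals$animal_id[animals$class == cl]))
    f <- ((seq_along(ids) - 1L + offset) %% k) + 1L
    offset <- offset + length(ids)          # stagger classes across folds
    names(f) <- ids
    fold_of <- c(fold_of, f)
  }
  fold_of
}

#' Spectrum-level fold vector from an animal-level fold map
#'
#' @param fold_of Named fold map from [kfold_plan()].
#' @param animal_ids Per-spectrum animal ids.
#' @return Integer fold index per spectrum.
#' @export
fold_vector <- function(fold_of, animal_ids) {
  unname(fold_of[as.character(animal_ids)])
}

#' Choose the number of latent variables by k-fold cross-validation
#'
#' For each candidate count `A = 1..max_lv`, fits one `max_lv`-component
#' NIPALS model per fold-complement and scores held-out spectra with the
#' first `A` components (the sequential structure of NIPALS makes the
#' truncated predictions exact). The chosen count is the smallest `A`
#' whose cross-validated objective is within one standard error of the
#' minimum (parsimony rule). Objectives: root-mean-square error of
#' cross-validation for regression, misclassification rate for
#' discriminant analysis (argmax over dummy columns).
#'
#' @param X Predictor matrix (already preprocessed, unless `pipeline` is
#'   given).
#' @param Y Response matrix/vector (concentrations, or one-hot dummy
#'   matrix for DA).
#' @param folds Integer fold index per row of `X` (see [fold_vector()]).
#' @param max_lv Largest candidate component count.
#' @param objective "rmse" or "misclass".
#' @param pipeline Optional unfitted `pp_pipeline`; when given it is
#'   refitted on every fold-complement and applied to the held-out fold, so
#'   no preprocessing statistic leaks across folds.
#' @param grid Wavenumber grid, required when `pipeline` is given.
#' @return List with `n_lv` (selected), `cv` (mean objective per A),
#'   `cv_se` (standard error per A across folds).
#' @export
select_lv <- function(X, Y, folds, max_lv, objective = c("rmse", "misclass"),
                      pipeline = NULL, grid = NULL) {
  objective <- match.arg(objective)
  X <- as.matrix(X); Y <- as.matrix(Y)
  ks <- sort(unique(folds))
  if (length(ks) < 2) stop("need at least 2 folds")
  max_lv <- min(max_lv, min(vapply(ks, function(k) sum(folds != k), integer(1))) - 1L)
  per_fold <- matrix(NA_real_, length(ks), max_lv)
  for (i in seq_along(ks)) {
    tr <- folds != ks[i]
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[!tr, , drop = FALSE]
    if (!is.null(pipeline)) {
      pp <- fit_apply_pipeline(pipeline, Xtr, Xte, grid)
      Xtr <- pp$X_train; Xte <- pp$X_test
    }
    fit <- fit_pls(Xtr, Y[tr, , drop = FALSE], n_lv = max_lv)
    for (A in seq_len(max_lv)) {
      Yhat <- predict(fit, Xte, n_lv = A)
      per_fold[i, A] <- if (objective == "rmse") {
        sqrt(mean((Y[!tr, , drop = FALSE] - Yhat)^2))
      } else {
        mean(max.col(Yhat, ties.method = "first") !=
               max.col(Y[!tr, , drop = FALSE], ties.method = "first"))
      }
    }
  }
  cv <- colMeans(per_fold)
  cv_se <- apply(per_fold, 2, stats::sd) / sqrt(length(ks))
  best <- which.min(cv)
  n_lv <- which(cv <= cv[best] + cv_se[best])[1]   # one-SE parsimony rule
  list(n_lv = n_lv, cv = cv, cv_se = cv_se)
}
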