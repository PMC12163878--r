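# Spectra I/O (wide CSV + metadata sidecar), VIP band reporting, and the
# end-to-end study pipeline.

#' Write a spectra set to CSV
#'
#' Wide format: header row of wavenumbers preceded by a `spectrum_id`
#' column, one row per spectrum; metadata goes to a sidecar CSV keyed on
#' `spectrum_id`.
#'
#' @param spectra A `spectra_set`.
#' @param path Spectra CSV path.
#' @param meta_path Metadata sidecar path (default: `path` with
#'   `_meta.csv` suffix).
#' @return Invisibly, the two paths.
#' @export
write_spectra <- function(spectra, path, meta_path = sub("\\.csv$", "_meta.csv", path)) {
  stopifnot(inherits(spectra, "spectra_set"))
  df <- data.frame(spectrum_id = spectra$meta$spectrum_id, spectra$absorbance,
                   check.names = FALSE)
  colnames(df) <- c("spectrum_id", format(spectra$wavenumbers, trim = TRUE, scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  utils::write.csv(spectra$meta, meta_path, row.names = FALSE)
  invisible(c(path, meta_path))
}

#' Read a spectra set from CSV
#'
#' Inverse of [write_spectra()]. The grid must be strictly monotone; an
#' ascending grid is accepted and reversed to the descending mid-IR
#' convention with a warning. Metadata is joined on `spectrum_id` and must
#' cover every spectrum.
#'
#' @param path Spectra CSV path.
#' @param meta_path Metadata sidecar path.
#' @return A `spectra_set`.
#' @export
read_spectra <- function(path, meta_path = sub("\\.csv$", "_meta.csv", path)) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "spectrum_id") stop("first column must be spectrum_id")
  wn <- as.numeric(names(df)[-1])
  if (any(is.na(wn))) stop("non-numeric wavenumber in header")
  X <- as.matrix(df[, -1, drop = FALSE])
  d <- diff(wn)
  if (all(d > 0)) {
    warning("ascending wavenumber grid; reversing to descending convention")
    wn <- rev(wn); X <- X[, rev(seq_along(wn)), drop = FALSE]
  } else if (!all(d < 0)) stop("wavenumber grid must be strictly monotone")
  meta <- utils::read.csv(meta_path)
  missing <- setdiff(df$spectrum_id, meta$spectrum_id)
  if (length(missing)) stop("metadata missing spectrum id(s): ", paste(missing, collapse = ", "))
  meta <- meta[match(df$spectrum_id, meta$spectrum_id), ]
  rownames(meta) <- NULL
  dimnames(X) <- list(df$spectrum_id, NULL)
  spectra_set(wn, X, meta)
}

#' Contiguous high-VIP wavenumber regions
#'
#' Maximal runs of grid points whose VIP score is at or above `threshold`,
#' reported as `(low, high)` intervals in cm-1 and filtered to a minimum
#' width. VIP ~ 1 is the conventional "important variable" cutoff (the
#' mean squared VIP is exactly 1).
#'
#' @param vip_scores VIP vector aligned to `grid`.
#' @param grid Descending wavenumber vector.
#' @param threshold VIP cutoff (default 1.0).
#' @param min_width Minimum interval width in cm-1.
#' @return Data frame with columns `low`, `high` (possibly zero rows).
#' @export
vip_regions <- function(vip_scores, grid, threshold = 1.0, min_width = 0) {
  if (length(vip_scores) != length(grid)) stop("vip and grid must align")
  above <- vip_scores >= threshold
  if (!any(above)) return(data.frame(low = numeric(0), high = numeric(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  out <- data.frame(low = pmin(grid[runs$start], grid[runs$end]),
                    high = pmax(grid[runs$start], grid[runs$end]))
  out <- out[out$high - out$low >= min_width, , drop = FALSE]
  out[order(out$low), , drop = FALSE]
}

#' Run the full iron-overload study pipeline
#'
#' Generates (or accepts) a cohort, then runs every stage of the study:
#' preprocessing, replicate-aware split, binary PLS-DA (control vs all
#' iron-dosed), four-class and three-class PLS-DA (250 + 500 merged),
#' five per-tissue PLS regressions, permutation tests of the binary
#' classifier and the blood regression, the summary-statistics
#' significance table, and VIP band reporting for the binary model.
#'
#' @param design A `cohort_design` (used when `spectra` is NULL).
#' @param spectra Optional pre-built `spectra_set`.
#' @param pipeline Preprocessing pipeline; default truncates to the
#'   fingerprint region (1800--900 cm-1) and applies SNV.
#' @param test_fraction,k,max_lv Split and cross-validation settings.
#' @param B Permutation count (0 skips the permutation stage).
#' @param seed Master seed; stage seeds are derived from it by fixed
#'   offsets (split +1, folds +2, permutations +3).
#' @param tissues Tissues to regress (default all five).
#' @return List of stage results: `classification` (metrics per task),
#'   `regression` (Table-5-shaped data frame), `permutation`,
#'   `univariate`, `vip_regions`, `split`, `seed`.
#' @export
run_iron_pipeline <- function(design = cohort_design(), spectra = NULL,
                              pipeline = pp_pipeline(pp_step("truncate", low = 900, high = 1800),
                                                     pp_step("snv")),
                              test_fraction = 0.30, k = 5L, max_lv = 15L,
                              B = 100L, seed = 1L,
                              tissues = c("blood", "spleen", "heart", "liver", "kidney")) {
  if (is.null(spectra)) {
    design$seed <- seed
    spectra <- generate_cohort(design)
  }
  meta <- spectra$meta
  grid <- spectra$wavenumbers
  plan <- stratified_group_split(meta, test_fraction, seed = seed + 1L)
  tr <- meta$animal_id %in% plan$train_ids
  te <- meta$animal_id %in% plan$test_ids

  tasks <- list(
    binary = regroup_classes(meta$class, c(`250` = "iron", `500` = "iron", `1000` = "iron"),
                             keep_unmapped = TRUE),
    four_class = as.character(meta$class),
    three_class = regroup_classes(meta$class, c(`250` = "mid", `500` = "mid"),
                                  keep_unmapped = TRUE)
  )
  fold_of <- kfold_plan(meta, plan$train_ids, k = k, seed = seed + 2L)
  folds <- fold_vector(fold_of, meta$animal_id[tr])

  classification <- list()
  binary_model <- NULL
  for (task in names(tasks)) {
    labels <- tasks[[task]]
    Y <- dummy_code(labels[tr])
    sel <- select_lv(spectra$absorbance[tr, ], Y, folds, max_lv = max_lv,
                     objective = "rmse", pipeline = pipeline, grid = grid)
    pp <- fit_apply_pipeline(pipeline, spectra$absorbance[tr, ], spectra$absorbance[te, ], grid)
    model <- fit_plsda(pp$X_train, labels[tr], n_lv = sel$n_lv)
    classification[[task]] <- list(
      n_lv = sel$n_lv,
      train = classification_metrics(labels[tr], predict(model, pp$X_train), model$classes),
      test = classification_metrics(labels[te], predict(model, pp$X_test), model$classes))
    if (task == "binary") {
      binary_model <- model
      binary_grid <- pp$grid
    }
  }

  regression <- lapply(tissues, function(tt)
    fit_tissue_regression(spectra, tt, plan, pipeline = pipeline,
                          max_lv = max_lv, k = k, seed = seed + 2L))
  names(regression) <- tissues
  regression_table <- do.call(rbind, lapply(regression, `[[`, "metrics"))

  permutation <- NULL
  if (B > 0) {
    n_lv_bin <- classification$binary$n_lv
    # reliability metric for the classifier permutation: test-set RMSE on the
    # dummy-coded response (continuous, so the empirical floor is attainable
    # even under class imbalance, where accuracy ties at its ceiling)
    eval_binary <- function(y) {
      pp <- fit_apply_pipeline(pipeline, spectra$absorbance[tr, ], spectra$absorbance[te, ], grid)
      m <- fit_plsda(pp$X_train, y[tr], n_lv = n_lv_bin)
      sc <- predict(m, pp$X_test, type = "score")
      sqrt(mean((dummy_code(y[te], m$classes) - sc)^2))
    }
    n_lv_blood <- regression$blood$metrics$n_lv
    eval_blood <- function(y) {
      pp <- fit_apply_pipeline(pipeline, spectra$absorbance[tr, ], spectra$absorbance[te, ], grid)
      m <- fit_pls(pp$X_train, y[tr], n_lv = n_lv_blood)
      rmse(y[te], drop(predict(m, pp$X_test)))
    }
    permutation <- list(
      binary_dummy_rmse = permutation_test(eval_binary, tasks$binary, meta$animal_id,
                                           B = B, direction = "lower", seed = seed + 3L),
      blood_rmse = permutation_test(eval_blood, meta$blood, meta$animal_id,
                                    B = B, direction = "lower", seed = seed + 3L))
  }

  univariate <- summary_significance_table(design$tissue_params, design$group_sizes)
  vips <- vip(binary_model$core)
  regions <- vip_regions(vips, binary_grid, threshold = 1.0, min_width = 8)

  list(classification = classification, regression = regression_table,
       regression_fits = regression, permutation = permutation,
       univariate = univariate, vip = vips, vip_grid = binary_grid,
       vip_regions = regions, split = plan, seed = seed)
}
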