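# Permutation validation: refit the full pipeline under animal-level
# label/response permutations and compare the original metric with the
# empirical null.

#' Permutation test of a model-fitting procedure
#'
#' Permutes the response at the animal level -- all replicate spectra of an
#' animal move together, preserving the class/concentration multiset over
#' animals -- refits the supplied procedure on each permuted response and
#' records its test metric. The empirical p-value uses the plus-one
#' correction, `(#{permuted at least as good} + 1) / (B + 1)`, so it can
#' never return zero.
#'
#' @param fit_eval Function `(y) -> metric` that runs the entire modelling
#'   procedure (split, preprocessing, fit, evaluation) for a response
#'   vector aligned with the spectra and returns a scalar metric.
#'   It must be deterministic given `y`.
#' @param y Original response (class labels or concentrations), one per
#'   spectrum.
#' @param animal_ids Animal id per spectrum (replicates share one id).
#' @param B Number of permutations (the study used 500).
#' @param direction "higher" if larger metric values are better (accuracy),
#'   "lower" if smaller are better (RMSE).
#' @param seed Integer seed for the permutation stream.
#' @return A `permutation_result`: list with `original`, `permuted`
#'   (length-B vector), `p_value`, `direction`, `B`, `seed`.
#' @export
permutation_test <- function(fit_eval, y, animal_ids, B = 500L,
                             direction = c("higher", "lower"), seed = 1L) {
  direction <- match.arg(direction)
  if (B < 1) stop("B must be >= 1")
  animal_ids <- as.character(animal_ids)
  animals <- unique(animal_ids)
  y_animal <- y[match(animals, animal_ids)]          # animal-level response
  if (!all(vapply(animals, function(a) length(unique(y[animal_ids == a])) == 1, logical(1))))
    stop("response must be constant within an animal")
  original <- fit_eval(y)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  permuted <- vapply(seq_len(B), function(b) {
    y_perm_animal <- sample(y_animal)
    y_perm <- y_perm_animal[match(animal_ids, animals)]
    fit_eval(y_perm)
  }, numeric(1))
  extreme <- if (direction == "higher") sum(permuted >= original) else sum(permuted <= original)
  structure(list(original = original, permuted = permuted,
                 p_value = (extreme + 1) / (B + 1),
                 direction = direction, B = B, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation test: original %.4f vs %d permutations (%s is better); p = %.4g\n",
              x$original, x$B, if (x$direction == "higher") "higher" else "lower", x$p_value))
  invisible(x)
}
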