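# Small deterministic fixtures shared across test files.

# tissue parameter table for an arbitrary set of class labels (subset of the
# default table, relabelled), so tiny cohorts can be built quickly
tiny_tissue_params <- function(classes) {
  ref <- tissue_iron_reference()
  ref[ref$class %in% classes, ]
}

# a small two-class design: fast to generate, still dose-structured
tiny_design <- function(seed = 1L, noise_sd = 0.002, ...) {
  cohort_design(group_sizes = c(control = 4L, `1000` = 4L),
                tissue_params = tiny_tissue_params(c("control", "1000")),
                seed = seed, noise_sd = noise_sd, ...)
}

# spectra_set with a single linear band: y recoverable exactly
linear_band_set <- function(n = 20, p = 40, seed = 1) {
  set.seed(seed)
  grid <- seq(2000, 2000 - 4 * (p - 1), by = -4)
  band <- exp(-0.5 * ((grid - 1900) / 20)^2)
  y <- runif(n, 1, 10)
  X <- outer(y, band) + matrix(runif(n * p, 0, 0.01) * 0, n, p)
  meta <- data.frame(spectrum_id = sprintf("s%02d", 1:n),
                     animal_id = sprintf("a%02d", 1:n),
                     replicate = 1L,
                     class = rep(c("lo", "hi"), length.out = n),
                     blood = y)
  spectra_set(grid, X, meta)
}
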