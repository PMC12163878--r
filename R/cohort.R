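# Synthetic iron-overload cohort: animals, tissue iron, triplicate serum spectra.

#' Reference tissue iron concentrations by dose class
#'
#' Mean and standard deviation of iron concentration per tissue and dose
#' class used as ground truth by the cohort generator: blood, heart, liver,
#' spleen and kidney for a control group and three iron-dextran doses
#' (250, 500 and 1000 mg/kg). Units are the assay's reporting units per
#' tissue and are treated as opaque throughout.
#'
#' @return A data frame with columns `tissue`, `class`, `mean`, `sd`.
#' @export
tissue_iron_reference <- function() {
  cls <- c("control", "250", "500", "1000")
  ref <- rbind(
    data.frame(tissue = "blood",  class = cls, mean = c(215, 2920, 6085, 16914), sd = c(30, 468, 1646, 5077)),
    data.frame(tissue = "heart",  class = cls, mean = c(337, 759, 1346, 2316),   sd = c(59, 93, 270, 355)),
    data.frame(tissue = "liver",  class = cls, mean = c(253, 5712, 7472, 9885),  sd = c(79, 744, 544, 710)),
    data.frame(tissue = "spleen", class = cls, mean = c(1903, 11415, 13977, 18708), sd = c(1623, 2267, 2008, 2787)),
    data.frame(tissue = "kidney", class = cls, mean = c(213, 664, 968, 2391),    sd = c(77, 157, 251, 618))
  )
  ref$class <- factor(ref$class, levels = cls)
  ref
}

#' Cohort design for the synthetic iron-overload study
#'
#' Describes everything the generator needs: group sizes, replicate count,
#' the wavenumber grid (descending, mid-IR convention), per-tissue iron
#' distributions per dose class, the spectral regions carrying dose signal,
#' and the replicate-level artifact magnitudes (multiplicative scatter,
#' smooth baseline drift, additive noise).
#'
#' Defaults reproduce the study design: 10/14/13/15 animals in the control,
#' 250, 500 and 1000 mg/kg groups, triplicate spectra (156 in total), a
#' 4000--400 cm-1 grid at 4 cm-1 step, and dose signal confined to the
#' 1125--1250, 1280--1330 and 1350--1450 cm-1 regions.
#'
#' @param group_sizes Named integer vector, animals per dose class.
#' @param replicates_per_animal Spectra acquired per animal.
#' @param grid_start,grid_end,grid_step Wavenumber grid in cm-1;
#'   `grid_start > grid_end` (descending).
#' @param tissue_params Data frame with columns `tissue`, `class`, `mean`,
#'   `sd` giving the iron concentration distribution per tissue and class.
#' @param signal_regions List of `c(low, high)` wavenumber intervals (cm-1)
#'   in which dose-dependent absorbance change is injected.
#' @param signal_amplitudes Per-region amplitude coefficients (absorbance
#'   units per unit of saturating dose response).
#' @param signal_scale Concentration scale (blood units) of the saturating
#'   dose response `log1p(iron_blood / signal_scale)`.
#' @param severity_cor Correlation between the shared animal-level severity
#'   factor and each tissue's iron draw; makes tissue iron predictable from
#'   blood-driven spectra.
#' @param bio_band_sd Between-animal biological variability: SD of the
#'   multiplicative jitter applied once per animal to every base band
#'   amplitude (replicates share it). Creates the animal-level
#'   generalization gap real cohorts show.
#' @param noise_sd Additive noise SD (absorbance units).
#' @param scatter_slope_range,scatter_offset_range Uniform ranges of the
#'   per-replicate multiplicative scatter slope and offset.
#' @param baseline_degree,baseline_coef_range Degree and uniform coefficient
#'   range of the random smooth per-replicate baseline polynomial (evaluated
#'   on the grid rescaled to [0, 1]).
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the design including this seed.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(group_sizes = c(control = 10L, `250` = 14L, `500` = 13L, `1000` = 15L),
                          replicates_per_animal = 3L,
                          grid_start = 4000, grid_end = 400, grid_step = 4,
                          tissue_params = tissue_iron_reference(),
                          signal_regions = list(c(1125, 1250), c(1280, 1330), c(1350, 1450)),
                          signal_amplitudes = c(0.080, 0.080, 0.075),
                          signal_scale = 10000,
                          severity_cor = 0.9,
                          bio_band_sd = 0.04,
                          noise_sd = 0.002,
                          scatter_slope_range = c(0.9, 1.1),
                          scatter_offset_range = c(-0.02, 0.02),
                          baseline_degree = 2L,
                          baseline_coef_range = c(-0.015, 0.015),
                          seed = 1L) {
  stopifnot(length(group_sizes) >= 1, !is.null(names(group_sizes)))
  if (any(group_sizes <= 0)) stop("all group sizes must be positive")
  if (replicates_per_animal < 1) stop("replicates_per_animal must be >= 1")
  if (!(grid_start > grid_end)) stop("grid must be descending: grid_start > grid_end")
  if (grid_step <= 0) stop("grid_step must be positive")
  if ((grid_start - grid_end) %% grid_step != 0)
    stop("grid span must be a multiple of grid_step")
  if (length(signal_regions) == 0) stop("signal_regions must be non-empty")
  for (r in signal_regions) {
    if (length(r) != 2 || r[1] >= r[2]) stop("each signal region must be c(low, high) with low < high")
    if (r[1] < grid_end || r[2] > grid_start) stop("signal region outside grid span")
  }
  if (length(signal_amplitudes) != length(signal_regions))
    stop("one amplitude per signal region required")
  stopifnot(all(c("tissue", "class", "mean", "sd") %in% names(tissue_params)))
  if (any(tissue_params$sd < 0)) stop("tissue SDs must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (bio_band_sd < 0) stop("bio_band_sd must be >= 0")
  if (scatter_slope_range[1] <= 0) stop("scatter slopes must stay positive")
  if (severity_cor < 0 || severity_cor > 1) stop("severity_cor must lie in [0, 1]")

  design <- list(
    group_sizes = group_sizes,
    replicates_per_animal = as.integer(replicates_per_animal),
    grid_start = grid_start, grid_end = grid_end, grid_step = grid_step,
    tissue_params = tissue_params,
    signal_regions = signal_regions,
    signal_amplitudes = signal_amplitudes,
    signal_scale = signal_scale,
    severity_cor = severity_cor,
    bio_band_sd = bio_band_sd,
    noise_sd = noise_sd,
    scatter_slope_range = scatter_slope_range,
    scatter_offset_range = scatter_offset_range,
    baseline_degree = as.integer(baseline_degree),
    baseline_coef_range = baseline_coef_range,
    seed = as.integer(seed)
  )
  class(design) <- "cohort_design"
  design
}

#' Wavenumber grid of a cohort design
#' @param design A `cohort_design`.
#' @return Numeric vector of wavenumbers in cm-1, strictly descending.
#' @export
design_grid <- function(design) {
  seq(design$grid_start, design$grid_end, by = -design$grid_step)
}

# Fixed serum-like band mixture shared by every animal: Gaussian bands at
# positions typical of dried-serum ATR spectra (amide A/I/II, CH stretches,
# carbohydrate / phosphate fingerprint bands). Amplitudes in absorbance units.
serum_base_bands <- function() {
  data.frame(
    center = c(3290, 2958, 2925, 2872, 1652, 1545, 1455, 1400, 1310, 1243, 1170, 1080, 1035, 920, 700),
    sigma  = c(120,  14,   16,   12,   26,   22,   16,   14,   12,   18,   15,   28,   16,   20, 60),
    amp    = c(0.25, 0.05, 0.08, 0.04, 0.45, 0.30, 0.08, 0.10, 0.04, 0.07, 0.03, 0.12, 0.08, 0.02, 0.05)
  )
}

# Saturating dose response mapping blood iron to perturbation strength.
dose_response <- function(iron_blood, scale) log1p(iron_blood / scale)

#' Noiseless serum spectrum for a given blood iron concentration
#'
#' The clean spectrum is a fixed mixture of Gaussian bands common to all
#' animals plus, inside each designated signal region, a window-limited
#' Gaussian perturbation whose amplitude grows as
#' `log1p(iron_blood / signal_scale)` -- monotone in blood iron and
#' saturating at high load. Outside the signal regions two clean spectra
#' differ by exactly zero.
#'
#' @param iron_blood Blood iron concentration (>= 0, Table-style units).
#' @param design A `cohort_design`.
#' @param band_amps Base band amplitudes; the default is the canonical
#'   serum mixture. [generate_cohort()] passes per-animal jittered
#'   amplitudes here to model biological between-animal variability.
#' @return Numeric vector of absorbances on `design_grid(design)`.
#' @export
clean_signal <- function(iron_blood, design, band_amps = NULL) {
  if (!inherits(design, "cohort_design")) stop("design must be a cohort_design")
  if (length(iron_blood) != 1 || is.na(iron_blood) || iron_blood < 0)
    stop("iron_blood must be a single non-negative concentration")
  wn <- design_grid(design)
  bands <- serum_base_bands()
  if (is.null(band_amps)) band_amps <- bands$amp
  x <- numeric(length(wn))
  for (i in seq_len(nrow(bands))) {
    x <- x + band_amps[i] * exp(-0.5 * ((wn - bands$center[i]) / bands$sigma[i])^2)
  }
  g <- dose_response(iron_blood, design$signal_scale)
  for (i in seq_along(design$signal_regions)) {
    r <- design$signal_regions[[i]]
    inside <- wn >= r[1] & wn <= r[2]
    # flat-top (Tukey) window: full amplitude over the central part of the
    # region, cosine-tapered to zero at its edges, exactly zero outside --
    # so the declared region is where the dose signal actually lives
    tpos <- (wn[inside] - r[1]) / (r[2] - r[1])
    alpha <- 0.25
    w <- rep(1, length(tpos))
    lo <- tpos < alpha
    hi <- tpos > 1 - alpha
    w[lo] <- 0.5 * (1 + cos(pi * (tpos[lo] / alpha - 1)))
    w[hi] <- 0.5 * (1 + cos(pi * ((tpos[hi] - 1 + alpha) / alpha)))
    x[inside] <- x[inside] + design$signal_amplitudes[i] * g * w
  }
  x
}

#' Apply multiplicative scatter to a spectrum
#'
#' The affine transform `a * spectrum + b` that standard normal variate and
#' multiplicative scatter correction are designed to undo.
#'
#' @param spectrum Numeric vector.
#' @param a Multiplicative slope, must be > 0.
#' @param b Additive offset.
#' @return `a * spectrum + b`.
#' @export
apply_scatter <- function(spectrum, a, b) {
  if (a <= 0) stop("scatter slope a must be > 0")
  a * spectrum + b
}

# One truncated-at-zero normal draw correlated with a shared latent severity.
# Conditional on z, the tissue draw is mean + sd*(rho*z + sqrt(1-rho^2)*eps);
# eps is redrawn until the value is positive (truncation of the conditional).
truncated_corr_draw <- function(mean, sd, z, rho) {
  if (sd == 0) return(max(mean, 0))
  repeat {
    eps <- stats::rnorm(1)
    val <- mean + sd * (rho * z + sqrt(1 - rho^2) * eps)
    if (val > 0) return(val)
  }
}

#' Generate the synthetic cohort
#'
#' Draws per-animal tissue iron concentrations (one truncated-at-zero normal
#' per tissue, coupled through a shared latent severity factor so organ and
#' blood iron are positively correlated), builds each animal's clean serum
#' spectrum from its blood iron, and produces each replicate by applying a
#' random multiplicative scatter, a random smooth polynomial baseline and
#' i.i.d. additive noise. Between-animal biological variability enters as
#' a multiplicative jitter on the base band amplitudes, drawn once per
#' animal and shared by its replicates. Fully deterministic given the
#' design (including its seed); randomness is consumed in a fixed
#' documented order (per animal: severity, tissues in the order of
#' `tissue_params`, band jitter; then per replicate: slope, offset,
#' baseline coefficients, noise).
#'
#' @param design A `cohort_design`.
#' @return A `spectra_set`: list with `wavenumbers`, `absorbance`
#'   (n_spectra x n_points matrix) and `meta` (one row per spectrum:
#'   `spectrum_id`, `animal_id`, `replicate`, `class`, and one iron column
#'   per tissue).
#' @export
generate_cohort <- function(design) {
  if (!inherits(design, "cohort_design")) stop("design must be a cohort_design")
  wn <- design_grid(design)
  tissues <- unique(design$tissue_params$tissue)
  classes <- names(design$group_sizes)
  n_animals <- sum(design$group_sizes)
  n_rep <- design$replicates_per_animal

  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(design$seed)

  meta <- vector("list", n_animals * n_rep)
  absorb <- matrix(NA_real_, nrow = n_animals * n_rep, ncol = length(wn))
  row <- 0L
  animal <- 0L
  for (cl in classes) {
    for (k in seq_len(design$group_sizes[[cl]])) {
      animal <- animal + 1L
      animal_id <- sprintf("A%02d_%s", animal, cl)
      z <- stats::rnorm(1)
      iron <- vapply(tissues, function(tt) {
        p <- design$tissue_params[design$tissue_params$tissue == tt &
                                    design$tissue_params$class == cl, ]
        if (nrow(p) != 1) stop("tissue_params must have one row per tissue x class")
        truncated_corr_draw(p$mean, p$sd, z, design$severity_cor)
      }, numeric(1))
      base_amps <- serum_base_bands()$amp
      amps <- base_amps * (1 + stats::rnorm(length(base_amps), 0, design$bio_band_sd))
      clean <- clean_signal(iron[["blood"]], design, band_amps = amps)
      xnorm <- seq(0, 1, length.out = length(wn))
      for (r in seq_len(n_rep)) {
        row <- row + 1L
        a <- stats::runif(1, design$scatter_slope_range[1], design$scatter_slope_range[2])
        b <- stats::runif(1, design$scatter_offset_range[1], design$scatter_offset_range[2])
        coefs <- stats::runif(design$baseline_degree + 1L,
                              design$baseline_coef_range[1], design$baseline_coef_range[2])
        baseline <- drop(outer(xnorm, 0:design$baseline_degree, `^`) %*% coefs)
        noise <- if (design$noise_sd > 0) stats::rnorm(length(wn), 0, design$noise_sd) else 0
        absorb[row, ] <- apply_scatter(clean, a, b) + baseline + noise
        meta[[row]] <- data.frame(
          spectrum_id = sprintf("%s_r%d", animal_id, r),
          animal_id = animal_id, replicate = r, class = cl,
          as.list(iron), stringsAsFactors = FALSE
        )
      }
    }
  }
  meta <- do.call(rbind, meta)
  meta$class <- factor(meta$class, levels = classes)
  rownames(absorb) <- meta$spectrum_id
  spectra_set(wn, absorb, meta)
}

#' Construct a spectra set
#'
#' The container used throughout: a shared descending wavenumber grid, an
#' absorbance matrix (rows = spectra) and per-spectrum metadata.
#'
#' @param wavenumbers Strictly descending numeric grid (cm-1).
#' @param absorbance Matrix, one row per spectrum, `length(wavenumbers)` columns.
#' @param meta Data frame with at least `spectrum_id`, `animal_id`,
#'   `replicate`, `class`; iron concentration columns are carried through.
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(wavenumbers, absorbance, meta) {
  absorbance <- as.matrix(absorbance)
  if (any(diff(wavenumbers) >= 0)) stop("wavenumbers must be strictly descending")
  if (ncol(absorbance) != length(wavenumbers))
    stop("absorbance must have one column per wavenumber")
  if (nrow(absorbance) != nrow(meta))
    stop("meta must have one row per spectrum")
  req <- c("spectrum_id", "animal_id", "replicate", "class")
  if (!all(req %in% names(meta)))
    stop("meta must contain: ", paste(req, collapse = ", "))
  # replicates of one animal must agree on class and iron values
  iron_cols <- setdiff(names(meta), req)
  chk <- meta[, c("animal_id", "class", iron_cols), drop = FALSE]
  if (nrow(unique(chk)) != length(unique(meta$animal_id)))
    stop("replicates of an animal must share class and iron values")
  structure(list(wavenumbers = wavenumbers, absorbance = absorbance, meta = meta),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("spectra_set: %d spectra (%d animals) x %d points, %.0f-%.0f cm-1\n",
              nrow(x$absorbance), length(unique(x$meta$animal_id)),
              length(x$wavenumbers), max(x$wavenumbers), min(x$wavenumbers)))
  cat("classes:", paste(sprintf("%s=%d", names(table(x$meta$class)),
                                table(x$meta$class)), collapse = " "), "(spectra)\n")
  invisible(x)
}

#' Subset a spectra set by spectrum index
#' @param x A `spectra_set`.
#' @param i Row (spectrum) indices or logical mask.
#' @return A `spectra_set` with the selected spectra.
#' @export
subset_spectra <- function(x, i) {
  spectra_set(x$wavenumbers, x$absorbance[i, , drop = FALSE], x$meta[i, , drop = FALSE])
}
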