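---
title: "Methods: chemometric detection and quantification of iron overload from serum mid-IR spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemometric detection and quantification of iron overload from serum mid-IR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ferromir)
```

## The problem

Systemic iron overload damages the liver, heart, spleen and kidneys, and
its tissue burden is normally assessed by biopsy or imaging. ferromir
implements a minimally invasive alternative that has been explored in
rodent models: dry a drop of serum on an ATR diamond, record its
mid-infrared absorbance spectrum, and learn two kinds of models from the
spectra --- PLS-DA classifiers that flag iron loading (and its severity
class), and PLS regressions that predict the iron concentration measured
in blood and in each organ. Because no spectra from such studies are
publicly deposited, the package ships a synthetic cohort generator that
reproduces the published study design closely enough that every stage of
the pipeline can be exercised and tested end to end.

## The synthetic cohort

`cohort_design()` encodes the study conditions: 52 animals in four dose
groups (control n = 10, and 250 / 500 / 1000 mg/kg iron-dextran with
n = 14 / 13 / 15), triplicate spectra per animal (156 spectra), and a
4000--400 cm^-1^ grid at 4 cm^-1^ steps (901 points, descending, the
mid-IR convention). Per-tissue iron concentrations are drawn from the
published per-class mean ± SD values (`tissue_iron_reference()`), using
truncated-at-zero normals --- necessary because, e.g., the control spleen
value 1903 ± 1623 would otherwise produce negative concentrations. The
published table does not state units (blood is plausibly µg/dL, organs
mg/kg dry weight); the generator treats them as opaque per-tissue units
throughout. The table's footnote says "standard deviation of the mean",
which could be read as SEM; the generator and all defaults read the
printed values as SDs, and a user who prefers the SEM reading can simply
rescale `tissue_params$sd` before generating.

Three design choices matter most:

* **Coupled tissue draws.** All five tissue values of one animal share a
  latent severity factor (correlation `severity_cor = 0.9`), so organ
  iron is predictable from blood-driven spectra --- the premise of the
  whole approach. Draws are truncated at zero by redrawing the
  tissue-specific component.
* **Saturating dose signal.** Each animal's clean spectrum is a fixed
  mixture of Gaussian serum bands (amide A/I/II, CH stretches,
  carbohydrate and phosphate fingerprint bands) plus a perturbation in
  three regions --- 1125--1250, 1280--1330 and 1350--1450 cm^-1^ --- whose
  amplitude grows as `log1p(iron_blood / signal_scale)`. The response is
  monotone but flattens at high load, which is why the intermediate dose
  classes are spectrally the most similar. `signal_scale = 10000` (about
  the top-dose blood mean) keeps the response near-linear over most of
  the observed range, so a linear PLS can recover concentrations with the
  R² pattern the method is supposed to show, while still compressing the
  top class. The perturbation has a flat-top (Tukey, taper 0.25) profile:
  full amplitude over the central part of each region, cosine-tapered to
  exactly zero at the region edges, so the declared intervals are the
  actual support of the dose signal and band-recovery tests have a
  well-defined ground truth. Amplitudes (0.080 / 0.080 / 0.075 AU per
  unit response) are of the size of mid-sized fingerprint bands.
* **Three artifact layers.** Each replicate applies multiplicative
  scatter (slope U(0.9, 1.1), offset U(-0.02, 0.02)), a random smooth
  degree-2 baseline (coefficients U(-0.015, 0.015) on the unit-scaled
  grid) and i.i.d. additive noise (SD 0.002 AU). On top of that, each
  *animal* carries a multiplicative jitter of the base band amplitudes
  (`bio_band_sd = 0.04`), shared by its replicates. This biological
  between-animal variability is what creates the calibration/test
  generalization gap (RMSEP > RMSEC) that real cohorts show; without it,
  a clean spectrum would be a pure function of blood iron and test error
  would not systematically exceed calibration error.

All randomness flows from one seed in a documented order (per animal:
severity, tissue draws, band jitter; per replicate: slope, offset,
baseline, noise), so a design is a complete, reproducible description of
a cohort.

What the generator does *not* emulate: instrument line shapes, water
vapor and CO~2~ bands, Mie scattering, detector nonlinearity, batch or
drying-pattern effects, and any iron-specific absorption (mid-IR has
none; the real signal is metabolic). Passing tests therefore demonstrate
that the *pipeline* is correct and that the method works under the
published design's geometry and noise scales --- not that it works on any
particular real instrument.

## Preprocessing

`pp_step()` / `pp_pipeline()` compose the operators the field uses, in an
explicit order, with a strict fit/apply contract: statistics estimated
from data (the MSC reference, the mean-centering vector) are computed on
training spectra only and frozen for test spectra.

* **SNV** centers each spectrum and scales it to unit SD; exact affine
  invariance, idempotent.
* **MSC** regresses each spectrum on a reference (training column mean by
  default) and returns `(x - b)/a`; per-row coefficients equal the OLS
  fit of spectrum on reference.
* **Savitzky--Golay** fits a local polynomial in a sliding window and
  evaluates its `deriv`-th derivative at the window centre, scaled per
  cm^-1^ (not per index, and sign-correct on the descending grid). At the
  spectrum ends the window is truncated and the polynomial refit on the
  available points rather than reflect-padded: no data are fabricated at
  the edges, and every output value is checkable against an explicit
  local refit.
* **airPLS** estimates the baseline by iteratively reweighted penalized
  least squares with a second-difference penalty: weights drop to zero on
  points above the running baseline and grow exponentially
  (`exp(iter * |d_i| / ||d||_1)`) on points below it, until the L1 mass of
  negative residuals falls below `tol` (default 0.001) of the spectrum's
  L1 norm or `max_iter = 50`. `lambda = 1e4` is a sensible default for a
  ~900-point grid; the sparse banded system is solved with Matrix.
* **truncate** restricts to a wavenumber window; the fingerprint default
  used throughout the analyses is 1800--900 cm^-1^ (the published work
  says only "fingerprint region"; the bounds are configurable).

The published preprocessing search (its supplementary tables) is not
available, so the package makes no claim about which combination that
study selected; the analyses here use truncate + SNV, which suffices on
the synthetic cohort, and `select_lv()` accepts any pipeline for
leak-free comparison of alternatives.

## The NIPALS PLS engine

`fit_pls()` is a bespoke NIPALS implementation (single- and
multi-response): mean-center X and Y (autoscaling available but off by
default, so R² matches standard definitions), then per component iterate
weight → score → Y-loading until the score changes by less than 1e-10
(at most 500 inner iterations), deflate both blocks, and accumulate
`B = W (P'W)^{-1} Q'`. Component signs are fixed by making the
largest-magnitude weight element positive, which removes NIPALS' sign
indeterminacy from serialized models. Scores are mutually orthogonal,
weights unit-norm, and with as many components as the rank the
predictions coincide with ordinary least squares --- both properties are
tested, along with agreement with an independent PLS implementation on
random problems.

`vip()` implements variable importance in projection,
`VIP_j = sqrt(p * sum_a SSY_a (w_ja/||w_a||)^2 / sum_a SSY_a)` with
`SSY_a = q_a'q_a t_a't_a`; the mean squared VIP is exactly 1, so VIP ≥ 1
is the usual "important variable" cutoff used by `vip_regions()` to
report contiguous high-importance bands in cm^-1^.

Models serialize to JSON at full precision (`write_pls_model()` /
`read_pls_model()`); a reloaded model reproduces predictions to 1e-12.

## Replicate-aware validation

All partitioning happens at the animal level: the three replicate
spectra of an animal never straddle a train/test split or a CV fold.
`stratified_group_split()` draws the 30% test partition independently
within each dose class (round-half-up per class, so the default cohort
tests on 3/4/4/5 animals); `kfold_plan()` deals animals class-stratified
round-robin into k = 5 folds. `select_lv()` runs the whole preprocessing
pipeline *inside* each fold (no leakage of the MSC reference or centering
across folds), computes the CV objective for every component count with
one `max_lv`-component fit per fold, and picks the smallest count within
one standard error of the minimum. The parsimony rule is a deliberate
choice --- a bare minimum overfits at these sample sizes; its tie-break
(smallest qualifying count) is deterministic.

For PLS-DA, the CV objective is the cross-validated RMSE of the
dummy-coded response rather than the misclassification rate. With ~10
training animals per fold-complement class, the misclassification curve
moves in coarse steps and the one-SE rule tends to stop at 2--3
components; the continuous objective tracks the same minimum but resolves
it reliably. Misclassification remains available via
`objective = "misclass"`.

## Classification and regression

`fit_plsda()` one-hot-codes the classes (also in the binary case, so rows
sum to 1 and one decision rule serves every task) and fits PLS2 on the
dummy matrix. The default decision rule is the argmax of the predicted
class scores with ties broken toward the first class; a thresholded rule
(score > 0.5, else "unassigned") is available.
`classification_metrics()` reports per-class one-vs-rest ACC,
sensitivity, specificity, FPR and FNR (FPR = 1 - spec and FNR = 1 - sens
hold exactly) plus the confusion matrix, at spectrum level (n = 156),
and the analysis scripts aggregate them as mean ± SD across ten random
splits --- the interpretation adopted for the published tables'
± figures, which the original text does not define. The three-class task
is built by `regroup_classes()` merging the 250 and 500 mg/kg doses.

`fit_tissue_regression()` selects components by the same replicate-aware
CV, fits on the calibration partition, and reports RMSEC/RMSEP, R²c/R²p,
and LoD/LoQ. The detection limits follow the pseudo-univariate
convention --- regress predicted on measured concentration over the
calibration samples, then `LoD = 3.3 s/b` and `LoQ = 10 s/b` from that
line's residual standard error and slope --- because the published table
reports LoD/LoQ without a formula; the multipliers are arguments.

## Permutation validation

`permutation_test()` permutes the response at the **animal** level
(replicates move together; permuting spectra individually would leak
replicate information into both partitions and overstate significance),
refits the supplied procedure B times, and reports the plus-one-corrected
empirical p-value `(#extreme + 1)/(B + 1)`, which can never be zero; with
the study's B = 500 the attainable floor is 1/501 ≈ 0.002. The component
count is held at the original model's CV choice during permutations
(refitting the selection B times is possible but changes nothing at these
sizes and multiplies the cost).

The classifier's permutation metric is the test-set RMSE of the
dummy-coded response (lower is better), not raw accuracy. The cohort is
imbalanced (42 of 52 animals are iron-dosed), and the accuracy of a
permuted model has a heavy upper tail: a permutation that concentrates
majority labels in the test set scores ACC near 1 even though the model
carries no class information, so an original model can never beat all
permutations and the empirical floor becomes unreachable. The continuous
discriminant metric has no such ceiling, behaves like the Q²-style
statistics standard in chemometric permutation validation, and is
correctly calibrated under the null (verified by simulation in the test
suite: the rejection rate at α = 0.05 over 50 signal-free cohorts sits
inside the exact binomial band). Accuracy or macro-sensitivity can still
be plugged in, and every result names the metric used.

## Univariate stage

`compare_groups()` reproduces the normality-gated comparison: Shapiro--
Wilk on each group at α = 0.05, then an unpaired t-test if both pass,
otherwise Mann--Whitney. The t-branch uses the Welch (unequal-variance)
form: the published per-group SDs differ by up to two orders of
magnitude, where a pooled test would be indefensible.
`welch_from_summary()` computes the same test from printed mean/SD/n
alone (Satterthwaite degrees of freedom), which is exactly what the
published concentration table provides, and
`summary_significance_table()` applies it to every dose-vs-control pair.

## Numerical choices and problem sizes

Defaults: NIPALS inner tolerance 1e-10 (relative, on the score), 500
inner iterations; airPLS λ = 1e4, tol = 1e-3, 50 iterations; SG windows
must be odd and longer than the polynomial order; LV search up to 15;
k = 5 folds; B = 500 permutations in the acceptance script and 100 in
the interactive drivers; degenerate inputs (constant spectra,
zero-variance responses, single-class labels, anti-correlated
calibrations) are rejected with identifiable errors rather than patched.
The test suite and the analysis scripts run the full 156-spectrum cohort
for split-level work and 10 seeds for across-split summaries; the
permutation calibration uses 50 signal-free cohorts of 20 animals with
B = 100. These sizes were chosen as the smallest at which the across-seed
summaries stabilize.

## Known limitations

* The generator's spectra are sums of Gaussian bands; real dried-serum
  spectra have correlated band structures and instrument artifacts the
  tests cannot probe.
* PLS is linear; the saturating dose response is handled only to the
  extent that extra components can bend the fit, which is why the
  top-dose class compresses and the spleen (largest relative SD at
  control) shows the weakest R².
* LoD/LoQ values depend on the pseudo-univariate convention; blank-based
  definitions would differ.
* Classification metrics are spectrum-level; animal-level majority voting
  typically looks better but hides replicate disagreement.
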