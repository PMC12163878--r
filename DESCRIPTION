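Package: ferromir
Title: Chemometric Detection and Quantification of Iron Overload from Serum Mid-IR Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A chemometric pipeline for identifying iron overload and
    quantifying iron concentrations in blood and organs (spleen, heart,
    liver, kidney) from attenuated-total-reflection mid-infrared serum
    spectra. Implements a synthetic cohort generator with dose-dependent
    spectral signal, spectral preprocessing (standard normal variate,
    multiplicative scatter correction, Savitzky-Golay smoothing and
    derivatives, airPLS baseline correction), a NIPALS partial least
    squares engine with VIP scores, replicate-aware train/test splitting
    and k-fold cross-validation for latent-variable selection, binary and
    multiclass PLS-DA with the usual classification figures of merit,
    PLS regression with RMSEC/RMSEP, R2, LoD and LoQ, animal-level
    permutation tests with empirical p-values, and normality-gated
    univariate group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    signal,
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
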