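# Univariate confirmation stage: normality-gated two-group comparisons and
# a Welch t-test computable from printed summary statistics.

#' Normality-gated two-group comparison
#'
#' Shapiro-Wilk on each group at level `alpha`; if both pass, an unpaired
#' Welch t-test (the groups' variances differ by orders of magnitude in
#' this setting, so the unequal-variance form is used), otherwise the
#' nonparametric Mann-Whitney test.
#'
#' @param a,b Sample vectors, each of length >= 3.
#' @param alpha Significance level for both the normality gate and the
#'   comparison (default 0.05).
#' @return A `group_comparison`: list with `test` ("t-test" or
#'   "mann-whitney"), `statistic`, `p_value`, `normality_p` (per group),
#'   `significant`.
#' @export
compare_groups <- function(a, b, alpha = 0.05) {
  if (length(a) < 3 || length(b) < 3) stop("each group needs n >= 3")
  sw_a <- stats::shapiro.test(a)$p.value
  sw_b <- stats::shapiro.test(b)$p.value
  if (sw_a >= alpha && sw_b >= alpha) {
    if (stats::sd(a) == 0 && stats::sd(b) == 0) stop("both groups constant; t-test undefined")
    ht <- stats::t.test(a, b)                       # Welch by default
    test <- "t-test"
  } else {
    ht <- stats::wilcox.test(a, b, exact = FALSE)
    test <- "mann-whitney"
  }
  structure(list(test = test, statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 normality_p = c(a = sw_a, b = sw_b),
                 alpha = alpha, significant = ht$p.value < alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g, p = %.4g (%ssignificant at %.2g)\n",
              x$test, x$statistic, x$p_value, if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' Welch t-test from summary statistics
#'
#' The unequal-variance two-sample t statistic with Satterthwaite degrees
#' of freedom, computed from group means, standard deviations and sizes
#' alone -- exactly what a published mean +/- SD table provides.
#'
#' @param mean_a,sd_a,n_a Summary statistics of group A.
#' @param mean_b,sd_b,n_b Summary statistics of group B.
#' @return List with `t`, `df`, `p_value` (two-sided).
#' @export
welch_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (n_a < 2 || n_b < 2) stop("group sizes must be >= 2")
  if (sd_a <= 0 || sd_b <= 0) stop("SDs must be positive")
  va <- sd_a^2 / n_a
  vb <- sd_b^2 / n_b
  t <- (mean_a - mean_b) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Dose-vs-control significance table from published summaries
#'
#' Runs [welch_from_summary()] for every tissue and dose class against the
#' control group of a mean/SD reference table.
#'
#' @param reference Data frame like [tissue_iron_reference()]:
#'   `tissue`, `class`, `mean`, `sd`.
#' @param group_sizes Named animal counts per class.
#' @param alpha Significance level.
#' @return Data frame: tissue, class, t, df, p_value, significant.
#' @export
summary_significance_table <- function(reference = tissue_iron_reference(),
                                       group_sizes = c(control = 10L, `250` = 14L,
                                                       `500` = 13L, `1000` = 15L),
                                       alpha = 0.05) {
  doses <- setdiff(unique(as.character(reference$class)), "control")
  rows <- list()
  for (tt in unique(reference$tissue)) {
    ctrl <- reference[reference$tissue == tt & reference$class == "control", ]
    for (cl in doses) {
      grp <- reference[reference$tissue == tt & reference$class == cl, ]
      w <- welch_from_summary(grp$mean, grp$sd, group_sizes[[cl]],
                              ctrl$mean, ctrl$sd, group_sizes[["control"]])
      rows[[length(rows) + 1]] <- data.frame(
        tissue = tt, class = cl, t = w$t, df = w$df,
        p_value = w$p_value, significant = w$p_value < alpha)
    }
  }
  do.call(rbind, rows)
}
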