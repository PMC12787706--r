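#' Root mean square error between paired measurements
#'
#' @param method,reference equal-length numeric vectors of paired values.
#' @return `sqrt(mean((method - reference)^2))`.
#' @export
rmse <- function(method, reference) {
  if (length(method) != length(reference))
    stop("method and reference must have equal length")
  sqrt(mean((method - reference)^2))
}

#' Bland-Altman agreement analysis
#'
#' Computes the paired differences `method - reference` and reports the
#' mean bias, the sample SD of the differences (n - 1 denominator), the
#' limits of agreement `bias +/- 1.96 SD` (the 1.96 multiplier is used
#' exactly, not a t quantile), the agreement rate (percentage of
#' differences falling within the LOA, boundaries counted as within),
#' Pearson correlation between the two series, and the RMSE. With
#' zero variance in either series the correlation is reported as
#' not computable (`NA`), never as 1.
#'
#' @param method,reference paired numeric vectors, length n >= 3.
#' @return An object of class `AgreementReport` with fields `n`, `bias`,
#'   `sd_diff`, `loa_low`, `loa_high`, `agreement_rate_pct`, `pearson_r`,
#'   `pearson_p`, `rmse`, plus the input vectors for plotting.
#' @export
bland_altman <- function(method, reference) {
  if (length(method) != length(reference))
    stop("method and reference must have equal length")
  n <- length(method)
  if (n < 3L) stop("need at least 3 paired values")
  if (!all(is.finite(method)) || !all(is.finite(reference)))
    stop("inputs must be finite")
  d <- method - reference
  bias <- mean(d)
  sd_d <- sd(d)
  loa <- bias + c(-1.96, 1.96) * sd_d
  agree <- 100 * mean(d >= loa[1] & d <= loa[2])
  if (sd(method) == 0 || sd(reference) == 0) {
    r <- NA_real_; p <- NA_real_
  } else {
    ct <- cor.test(method, reference)
    r <- unname(ct$estimate); p <- ct$p.value
  }
  structure(list(n = n, bias = bias, sd_diff = sd_d,
                 loa_low = loa[1], loa_high = loa[2],
                 agreement_rate_pct = agree,
                 pearson_r = r, pearson_p = p,
                 rmse = rmse(method, reference),
                 method = method, reference = reference),
            class = "AgreementReport")
}

#' @export
print.AgreementReport <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement (n = %d)\n", x$n))
  cat(sprintf("  bias %.4g, SD %.4g, LOA [%.4g, %.4g]\n",
              x$bias, x$sd_diff, x$loa_low, x$loa_high))
  cat(sprintf("  agreement rate %.1f%%, RMSE %.4g\n",
              x$agreement_rate_pct, x$rmse))
  if (is.na(x$pearson_r)) cat("  Pearson r not computable (zero variance)\n")
  else cat(sprintf("  Pearson r %.3f (p = %.3g)\n", x$pearson_r, x$pearson_p))
  if (!is.null(x$comparison))
    cat(sprintf("  group comparison: %s, p = %.3g\n",
                x$comparison$test_name, x$comparison$p_value))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Differences against pair means, with the bias (dotted) and limits of
#' agreement (dashed) as horizontal lines.
#'
#' @param x an [bland_altman()] report.
#' @param ... passed to [graphics::plot()].
#' @export
plot.AgreementReport <- function(x, ...) {
  means <- (x$method + x$reference) / 2
  d <- x$method - x$reference
  graphics::plot(means, d, xlab = "Mean of methods",
                 ylab = "Difference (method - reference)", ...)
  graphics::abline(h = x$bias, lty = 3)
  graphics::abline(h = c(x$loa_low, x$loa_high), lty = 2)
}

#' Normality-gated two-group comparison
#'
#' The decision tree used for method-comparison testing: Shapiro-Wilk
#' normality on each group; if both are normal (p >= alpha), Bartlett's
#' test of equal variances; if variances are equal, Student's t-test
#' (pooled variance); if either normality or homoscedasticity fails, the
#' Mann-Whitney U test.
#'
#' @param a,b numeric samples, each n >= 3.
#' @param alpha gate level for the normality and variance tests.
#' @return A list: `test_name` (`"Student t"` or `"Mann-Whitney U"`),
#'   `statistic`, `p_value`, `normal_a`, `normal_b` (Shapiro-Wilk p),
#'   `equal_var` (Bartlett p, or `NA` when not reached), `path` (human
#'   readable route).
#' @export
compare_groups <- function(a, b, alpha = 0.05) {
  if (length(a) < 3L || length(b) < 3L)
    stop("each group needs at least 3 values")
  sw_a <- shapiro.test(a)$p.value
  sw_b <- shapiro.test(b)$p.value
  bart_p <- NA_real_
  if (sw_a >= alpha && sw_b >= alpha) {
    bart_p <- bartlett.test(list(a, b))$p.value
    if (bart_p >= alpha) {
      tt <- t.test(a, b, var.equal = TRUE)
      return(list(test_name = "Student t",
                  statistic = unname(tt$statistic), p_value = tt$p.value,
                  normal_a = sw_a, normal_b = sw_b, equal_var = bart_p,
                  path = "normal + equal variance -> Student t"))
    }
    path <- "normal but unequal variance -> Mann-Whitney U"
  } else {
    path <- "non-normal group -> Mann-Whitney U"
  }
  wt <- suppressWarnings(wilcox.test(a, b))
  list(test_name = "Mann-Whitney U",
       statistic = unname(wt$statistic), p_value = wt$p.value,
       normal_a = sw_a, normal_b = sw_b, equal_var = bart_p, path = path)
}
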