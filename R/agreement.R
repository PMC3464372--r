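# Agreement and group-comparison statistics: two-way absolute-agreement ICC,
# one-way ANOVA, pooled t, hemispheric asymmetry, multiplicity adjustment.

#' Two-way absolute-agreement intraclass correlation, single measures
#'
#' The ICC(A,1) form: with mean squares from the two-way subjects x raters
#' decomposition (`MSR` rows/subjects, `MSC` columns/raters, `MSE` residual),
#'
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`.
#'
#' Absolute agreement charges systematic rater offsets to the denominator
#' (through `MSC`), unlike the consistency form. The same mean-squares formula
#' serves the two-way random and two-way mixed models; model choice affects
#' interpretation and CI labeling only. The confidence interval is the
#' F-distribution method of McGraw & Wong (1996) with Satterthwaite degrees of
#' freedom.
#'
#' @param table Numeric matrix or data frame: rows = subjects (n >= 2),
#'   columns = raters/methods (k >= 2), no missing cells.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return An object of class `icc_result`: `icc`, `msr`, `msc`, `mse`,
#'   `lower`, `upper`, `n`, `k`, `conf_level`.
#' @references Shrout & Fleiss (1979) Psychol Bull 86:420-428; McGraw & Wong
#'   (1996) Psychol Methods 1:30-46.
#' @export
#' @examples
#' icc_absolute_agreement(cbind(r1 = c(1, 3, 5, 7), r2 = c(2, 4, 6, 8)))
icc_absolute_agreement <- function(table, conf_level = 0.95) {
  x <- as.matrix(table)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("ratings table must have no missing cells", call. = FALSE)
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) {
    stop("need at least 2 subjects and 2 raters", call. = FALSE)
  }
  row_m <- rowMeans(x); col_m <- colMeans(x); grand <- mean(x)
  if (stats::var(row_m) < .Machine$double.eps * max(1, grand^2)) {
    stop(structure(
      class = c("stereovol_degenerate_table", "error", "condition"),
      list(message = "degenerate ratings table: zero between-subject variance",
           call = sys.call(-1))
    ))
  }
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  resid <- x - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  alpha <- 1 - conf_level
  if (1 - icc < 1e-12 || (msc <= 0 && mse <= 0)) {
    ci <- c(icc, icc)
  } else {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    denom <- (a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1))
    if (denom <= 0 || !is.finite(denom)) {
      ci <- c(icc, icc)
    } else {
      v <- (a * msc + b * mse)^2 / denom
      fl <- stats::qf(1 - alpha / 2, n - 1, v)
      fu <- stats::qf(1 - alpha / 2, v, n - 1)
      lower <- n * (msr - fl * mse) /
        (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
      upper <- n * (fu * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * fu * msr)
      ci <- c(lower, upper)
    }
  }
  structure(
    list(icc = icc, msr = msr, msc = msc, mse = mse,
         lower = ci[1], upper = ci[2], n = n, k = k, conf_level = conf_level),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf(
    "<icc_result> ICC(A,1) = %.4f, %d%% CI [%.4f, %.4f] (n = %d subjects, k = %d raters)\n",
    x$icc, round(100 * x$conf_level), x$lower, x$upper, x$n, x$k
  ))
  invisible(x)
}

new_group_test <- function(statistic, df, p, test, means, sds, ns,
                           degenerate = FALSE) {
  structure(
    list(statistic = statistic, df = df, p_value = p,
         adjusted_p = NA_real_, test = test, group_means = means,
         group_sds = sds, group_ns = ns, degenerate = degenerate),
    class = "group_test"
  )
}

#' One-way between-group ANOVA for two groups
#'
#' Fixed-effects univariate ANOVA on two independent groups; `F` on
#' `(1, n_a + n_b - 2)` degrees of freedom with the exact p-value from the F
#' distribution. For two groups `F` equals the square of the pooled-variance t
#' statistic.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @return An object of class `group_test` with `statistic`, `df`, `p_value`,
#'   group means/SDs/sizes; `degenerate = TRUE` flags zero within-group
#'   variance with unequal means (`F = Inf`, `p = 0`).
#' @export
#' @examples
#' anova_between(c(1, 2, 3), c(4, 5, 6)) # F = 13.5 on (1, 4)
anova_between <- function(values_a, values_b) {
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  if (length(a) < 2 || length(b) < 2 || anyNA(a) || anyNA(b)) {
    stop("each group needs >= 2 non-missing values", call. = FALSE)
  }
  na <- length(a); nb <- length(b)
  grand <- mean(c(a, b))
  ssb <- na * (mean(a) - grand)^2 + nb * (mean(b) - grand)^2
  ssw <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
  df2 <- na + nb - 2
  means <- c(a = mean(a), b = mean(b))
  sds <- c(a = stats::sd(a), b = stats::sd(b))
  if (ssw <= 0) {
    if (ssb <= 0) {
      return(new_group_test(0, c(1, df2), 1, "anova", means, sds, c(na, nb)))
    }
    return(new_group_test(Inf, c(1, df2), 0, "anova", means, sds, c(na, nb),
                          degenerate = TRUE))
  }
  f <- ssb / (ssw / df2)
  p <- stats::pf(f, 1, df2, lower.tail = FALSE)
  new_group_test(f, c(1, df2), p, "anova", means, sds, c(na, nb))
}

#' Pooled-variance two-sample t test
#'
#' @inheritParams anova_between
#' @return A `group_test` with the t statistic, df `(1, n_a + n_b - 2)`
#'   convention collapsed to the single error df, and the two-sided p-value.
#' @export
two_sample_t <- function(values_a, values_b) {
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  if (length(a) < 2 || length(b) < 2 || anyNA(a) || anyNA(b)) {
    stop("each group needs >= 2 non-missing values", call. = FALSE)
  }
  na <- length(a); nb <- length(b)
  df <- na + nb - 2
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / df
  means <- c(a = mean(a), b = mean(b))
  sds <- c(a = stats::sd(a), b = stats::sd(b))
  if (sp2 <= 0) {
    if (mean(a) == mean(b)) {
      return(new_group_test(0, df, 1, "t", means, sds, c(na, nb)))
    }
    tstat <- sign(mean(a) - mean(b)) * Inf
    return(new_group_test(tstat, df, 0, "t", means, sds, c(na, nb),
                          degenerate = TRUE))
  }
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * stats::pt(-abs(tstat), df)
  new_group_test(tstat, df, p, "t", means, sds, c(na, nb))
}

#' @export
print.group_test <- function(x, ...) {
  if (x$test == "anova") {
    cat(sprintf("<group_test> F(%d, %d) = %.3f, p = %.4g\n",
                x$df[1], x$df[2], x$statistic, x$p_value))
  } else {
    cat(sprintf("<group_test> t(%d) = %.3f, p = %.4g\n",
                x$df[1], x$statistic, x$p_value))
  }
  invisible(x)
}

#' Signed hemispheric asymmetry index
#'
#' `100 * (L - R) / ((L + R) / 2)`: the left-right volume difference as a
#' percentage of the mean hemispheric volume. Antisymmetric in its arguments
#' and bounded in (-200, 200) for positive volumes.
#'
#' @param left,right Positive volumes (vectorized).
#' @return Asymmetry index in percent.
#' @export
#' @examples
#' asymmetry_index(110, 90) # +20
asymmetry_index <- function(left, right) {
  if (any(!is.finite(left)) || any(!is.finite(right)) ||
      any(left <= 0) || any(right <= 0)) {
    stop("volumes must be positive", call. = FALSE)
  }
  100 * (left - right) / ((left + right) / 2)
}

#' Adjust p-values for multiple comparisons
#'
#' Bonferroni (default) or Holm step-down adjustment, clipped at 1.
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @param method `"bonferroni"` or `"holm"`.
#' @return Adjusted p-values, same length and order as `pvals`.
#' @export
adjust_pvalues <- function(pvals, method = c("bonferroni", "holm")) {
  method <- match.arg(method)
  p <- as.numeric(pvals)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = method)
}
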