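# Statistical reporting: unpaired Student's t-test and mean +/- SD, the
# summaries used for all bar-chart comparisons.

#' Unpaired two-sample Student's t-test
#'
#' Equal-variance (pooled) two-sample t-test with a two-sided p-value from
#' the t distribution on n1 + n2 - 2 degrees of freedom. Degenerate inputs
#' (zero pooled variance) follow the convention: equal means give p = 1;
#' unequal means with zero variance are an error. Set `welch = TRUE` for
#' the unequal-variance variant.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param alpha Significance level (default 0.05).
#' @param welch Use Welch's unequal-variance test instead of pooled.
#' @return List of class `t_test_result`: `t`, `df`, `p_value`,
#'   `significant`, `mean_a`, `mean_b`, `sd_a`, `sd_b`, `n_a`, `n_b`.
#' @export
unpaired_t_test <- function(group_a, group_b, alpha = 0.05, welch = FALSE) {
  assert_that(length(group_a) >= 2 && length(group_b) >= 2,
              "each group needs n >= 2")
  n1 <- length(group_a); n2 <- length(group_b)
  m1 <- mean(group_a); m2 <- mean(group_b)
  s1 <- sd(group_a); s2 <- sd(group_b)
  pooled_var <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  if (pooled_var == 0 && s1 == 0 && s2 == 0) {
    assert_that(m1 == m2, "degenerate variance: zero variance, unequal means")
    res <- list(t = 0, df = n1 + n2 - 2, p_value = 1)
  } else {
    tt <- t.test(group_a, group_b, var.equal = !welch)
    res <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                p_value = tt$p.value)
  }
  structure(c(res, list(significant = res$p_value < alpha,
                        mean_a = m1, mean_b = m2, sd_a = s1, sd_b = s2,
                        n_a = n1, n_b = n2, alpha = alpha)),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("t = %.4f, df = %.4g, p = %.4g (%s at alpha = %g)\n",
              x$t, x$df, x$p_value,
              if (x$significant) "significant" else "n.s.", x$alpha))
  cat(sprintf("group A: %.4g +/- %.4g (n = %d); group B: %.4g +/- %.4g (n = %d)\n",
              x$mean_a, x$sd_a, x$n_a, x$mean_b, x$sd_b, x$n_b))
  invisible(x)
}

#' Mean and sample standard deviation
#'
#' @param values Numeric vector, n >= 2.
#' @return Named numeric vector `c(mean, sd)`; SD uses the n - 1 denominator.
#' @export
mean_sd <- function(values) {
  assert_that(length(values) >= 2, "SD undefined for n < 2")
  c(mean = mean(values), sd = sd(values))
}
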