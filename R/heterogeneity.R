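#' Reconstruct a log-OR standard error from a printed confidence interval
#'
#' For a Wald interval symmetric on the log scale,
#' `se = (log(ci_high) - log(ci_low)) / (2 * 1.959964)`. Useful for
#' heterogeneity computations from published odds ratios.
#'
#' @param or_ odds ratio point estimate.
#' @param ci_low,ci_high 95% bounds, with `ci_low <= or_ <= ci_high`.
#' @return the standard error of the log odds ratio.
#' @export
se_from_ci <- function(or_, ci_low, ci_high) {
  .check(all(ci_low > 0 & ci_low <= or_ & or_ <= ci_high), "ci",
         "requires 0 < ci_low <= or_ <= ci_high")
  (log(ci_high) - log(ci_low)) / (2 * Z95)
}

#' Fixed-effect heterogeneity between estimates
#'
#' Cochran's Q about the inverse-variance pooled mean,
#' `Q = sum(w * (beta - pooled)^2)` with `w = 1/se^2`, the I-squared
#' statistic `max(0, (Q - df)/Q) * 100`, and the chi-square p-value with
#' `df = k - 1`. Invariant to group relabelling and to common rescaling of
#' all betas and SEs.
#'
#' @param beta vector of log-scale estimates (k >= 2).
#' @param se their standard errors.
#' @return a `het_result`: `q`, `df`, `i2` (percent), `pval`, `pooled`.
#' @export
cochran_q <- function(beta, se) {
  .check(length(beta) == length(se) && length(beta) >= 2, "beta",
         "need >= 2 estimates with SEs")
  .check(all(is.finite(se) & se > 0), "se", "must be positive and finite")
  w <- 1 / se^2
  pooled <- sum(w * beta) / sum(w)
  q <- sum(w * (beta - pooled)^2)
  df <- length(beta) - 1L
  structure(list(
    q = q, df = df,
    i2 = if (q > 0) max(0, (q - df) / q) * 100 else 0,
    pval = pchisq(q, df = df, lower.tail = FALSE),
    pooled = pooled
  ), class = "het_result")
}

#' Between-sex heterogeneity of two estimates
#'
#' Fixed-effect Q with one degree of freedom comparing a male and a female
#' estimate (any object carrying `beta` and `se`, e.g. an [mr_estimate][new_mr_estimate]
#' or a [clogit_result][clogit_fit]; or an `(or_, ci_low, ci_high)` triple
#' via [se_from_ci()]).
#'
#' @param est_m,est_f the two estimates.
#' @return a `het_result` with `df = 1`.
#' @export
sex_heterogeneity <- function(est_m, est_f) {
  pull <- function(e) {
    if (!is.null(e$beta) && !is.null(e$se)) return(c(e$beta, e$se))
    stop("estimate must carry `beta` and `se`", call. = FALSE)
  }
  m <- pull(est_m); f <- pull(est_f)
  cochran_q(c(m[1], f[1]), c(m[2], f[2]))
}

#' @export
print.het_result <- function(x, ...) {
  cat(sprintf("Q = %.3f (df %d), I2 = %.1f%%, p = %.3g\n",
              x$q, x$df, x$i2, x$pval))
  invisible(x)
}
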