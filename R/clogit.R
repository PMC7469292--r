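#' Standardize log-exposure within a cohort
#'
#' Adds a column `log_exposure_z`, the z-score of `log(exposure)` with
#' moments (mean and sample SD) computed over all subjects in scope —
#' pooled, or within sex for `sd_scope = "sex_specific"` (the default,
#' because every downstream model is sex-stratified). Effect estimates on
#' this column are per 1-SD of log-exposure.
#'
#' @param pairs cohort data frame with positive `exposure` (and `sex` for
#'   sex-specific scope).
#' @param sd_scope `"sex_specific"` or `"pooled"`.
#' @return the cohort with `log_exposure_z` added.
#' @export
standardize_log_exposure <- function(pairs, sd_scope = c("sex_specific", "pooled")) {
  sd_scope <- match.arg(sd_scope)
  bad <- which(!(pairs$exposure > 0) | is.na(pairs$exposure))
  if (length(bad)) {
    stop(sprintf("nonpositive exposure in record(s): %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  lx <- log(pairs$exposure)
  zscore <- function(x) {
    s <- sd(x)
    if (!is.finite(s) || s == 0)
      stop("exposure is constant in scope: zero standard deviation",
           call. = FALSE)
    (x - mean(x)) / s
  }
  if (sd_scope == "pooled" || !"sex" %in% names(pairs)) {
    pairs$log_exposure_z <- zscore(lx)
  } else {
    z <- numeric(length(lx))
    for (s in unique(pairs$sex)) {
      idx <- pairs$sex == s
      z[idx] <- zscore(lx[idx])
    }
    pairs$log_exposure_z <- z
  }
  pairs
}

# Build the within-pair difference design (case minus control) for the
# exact 1:1 conditional likelihood. Continuous covariates difference
# directly; categoricals are dummy-coded with "missing"/NA as its own
# level before differencing. Returns the matrix plus the pair ids used.
.pair_differences <- function(pairs, covariates) {
  stopifnot(all(c("pair_id", "case") %in% names(pairs)))
  tab <- table(pairs$pair_id, pairs$case)
  if (!all(tab == 1L)) {
    stop("pairs must be 1:1 (exactly one case and one control per pair_id)",
         call. = FALSE)
  }
  cases <- pairs[pairs$case == 1, ]
  ctrls <- pairs[pairs$case == 0, ]
  ctrls <- ctrls[match(cases$pair_id, ctrls$pair_id), ]

  cols <- list(exposure_z = cases$log_exposure_z - ctrls$log_exposure_z)
  for (v in covariates) {
    if (!v %in% names(pairs)) {
      stop(sprintf("covariate '%s' not found in cohort", v), call. = FALSE)
    }
    xc <- cases[[v]]; xk <- ctrls[[v]]
    if (is.numeric(xc)) {
      cols[[v]] <- xc - xk
    } else {
      xc <- as.character(xc); xk <- as.character(xk)
      xc[is.na(xc)] <- "missing"; xk[is.na(xk)] <- "missing"
      lv <- sort(unique(c(xc, xk)))
      for (l in lv[-1]) {  # first level is the reference
        cols[[paste0(v, "_", l)]] <- as.numeric(xc == l) - as.numeric(xk == l)
      }
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- cases$pair_id
  X
}

#' Conditional logistic regression for 1:1 matched pairs
#'
#' Maximizes the exact 1:1 conditional likelihood by its pair-difference
#' reduction: a binomial log-likelihood with no intercept on the case-minus
#' -control covariate differences, fitted by iteratively reweighted least
#' squares. Matching factors are absorbed by the pairing and must not be
#' entered as covariates. Categorical covariates are dummy-coded with any
#' missing value as its own `"missing"` level before differencing. Pairs
#' with all-zero differences are uninformative and do not alter the
#' estimate.
#'
#' @param pairs cohort data frame carrying `pair_id`, `case`, and
#'   `log_exposure_z` (see [standardize_log_exposure()]).
#' @param covariates character vector of adjustment covariates (empty for
#'   the crude model).
#' @return a `clogit_result`: `coefficients` (with SEs), `or_per_sd`,
#'   `ci_low`, `ci_high`, `pval` for the exposure term, `n_pairs_used`
#'   (informative pairs), and convergence diagnostics.
#' @export
clogit_fit <- function(pairs, covariates = character(0)) {
  if (!"log_exposure_z" %in% names(pairs)) {
    stop("run standardize_log_exposure() before clogit_fit()", call. = FALSE)
  }
  X <- .pair_differences(pairs, covariates)
  informative <- rowSums(X != 0) > 0
  if (!any(informative)) stop("zero informative pairs", call. = FALSE)
  fit <- suppressWarnings(
    glm.fit(X, rep(1, nrow(X)), family = binomial(), intercept = FALSE)
  )
  cf <- coef(fit)
  if (any(!is.finite(cf)) || any(abs(cf) > 15) || !fit$converged) {
    off <- names(cf)[which.max(abs(cf))]
    stop(sprintf("conditional logistic fit did not converge (possible complete separation in '%s')",
                 off), call. = FALSE)
  }
  # observed information of the pair-difference likelihood
  p <- 1 / (1 + exp(-drop(X %*% cf)))
  W <- p * (1 - p)
  V <- solve(crossprod(X * W, X))
  ses <- sqrt(diag(V))
  b <- cf[["exposure_z"]]; s <- ses[[1]]
  structure(list(
    coefficients = data.frame(term = colnames(X), beta = unname(cf),
                              se = unname(ses),
                              pval = 2 * pnorm(-abs(unname(cf) / unname(ses))),
                              stringsAsFactors = FALSE),
    vcov = V,
    beta = b, se = s,
    or_per_sd = exp(b), ci_low = exp(b - Z95 * s), ci_high = exp(b + Z95 * s),
    pval = 2 * pnorm(-abs(b / s)),
    n_pairs_used = sum(informative), n_pairs = nrow(X),
    converged = fit$converged, iter = fit$iter
  ), class = "clogit_result")
}

#' @export
print.clogit_result <- function(x, ...) {
  cat(sprintf("conditional logistic (1:1): OR per 1-SD %.3f (95%% CI %.3f-%.3f), p %.3g; %d informative pairs\n",
              x$or_per_sd, x$ci_low, x$ci_high, x$pval, x$n_pairs_used))
  invisible(x)
}
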