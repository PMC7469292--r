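#' Construct an MR estimate
#'
#' Container for a causal-effect estimate on the log-OR-per-1-SD scale. The
#' odds ratio and 95% bounds are `exp(beta +/- 1.959964 * se)`; the p-value
#' is two-sided normal unless a t degrees-of-freedom is supplied.
#'
#' @param method label of the estimator.
#' @param beta,se point estimate (log-OR per 1-SD) and standard error.
#' @param n_snps number of instruments used.
#' @param extras named list of method-specific diagnostics.
#' @param df if finite, p from a t-distribution with this df.
#' @return an `mr_estimate`.
#' @export
new_mr_estimate <- function(method, beta, se, n_snps, extras = list(),
                            df = Inf) {
  pval <- if (is.finite(df)) 2 * pt(-abs(beta / se), df = df)
          else 2 * pnorm(-abs(beta / se))
  structure(list(
    method = method, beta = beta, se = se,
    or_ = exp(beta), ci_low = exp(beta - Z95 * se),
    ci_high = exp(beta + Z95 * se),
    pval = max(pval, .Machine$double.xmin), n_snps = n_snps, extras = extras
  ), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: OR %.3f (95%% CI %.3f-%.3f), beta %.4f (SE %.4f), p %.3g, k = %d\n",
              x$method, x$or_, x$ci_low, x$ci_high, x$beta, x$se, x$pval,
              x$n_snps))
  invisible(x)
}

.inst_df <- function(set) {
  stopifnot(inherits(set, "instrument_set"))
  set$instruments
}

#' Single-variant Wald ratio
#'
#' The causal estimate from one instrument: outcome effect divided by
#' exposure effect, `beta = by / bx`. The default standard error is the
#' first-order delta-method form `sy / |bx|`; `second_order = TRUE` adds
#' the exposure-uncertainty term,
#' `sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)`.
#'
#' @param inst one harmonized instrument: a 1-row instrument data frame, a
#'   1-variant `instrument_set`, or a list with `bx`, `sx`, `by`, `sy`.
#' @param second_order use the second-order delta-method SE.
#' @return an `mr_estimate`.
#' @export
wald_ratio <- function(inst, second_order = FALSE) {
  if (inherits(inst, "instrument_set")) inst <- .inst_df(inst)
  if (is.data.frame(inst)) {
    stopifnot(nrow(inst) == 1)
    inst <- as.list(inst)
  }
  if (inst$bx == 0) stop("undefined ratio: bx = 0", call. = FALSE)
  beta <- inst$by / inst$bx
  se <- if (second_order)
    sqrt(inst$sy^2 / inst$bx^2 + inst$by^2 * inst$sx^2 / inst$bx^4)
  else inst$sy / abs(inst$bx)
  new_mr_estimate("wald_ratio", beta, se, 1L)
}

#' Inverse-variance weighted estimator, multiplicative random effects
#'
#' Weighted regression of outcome on exposure effects through the origin
#' with weights `1/sy^2`:
#' `beta = sum(bx*by/sy^2) / sum(bx^2/sy^2)`. The fixed-effect SE is
#' inflated by `sqrt(max(1, Q/(k-1)))`, the multiplicative random-effects
#' scale, where `Q` is Cochran's statistic of the per-variant ratios about
#' the IVW estimate. `extras` carries `Q`, its df, and the fixed-effect SE.
#'
#' @param set an `instrument_set` with at least 2 variants.
#' @return an `mr_estimate`.
#' @export
ivw_mre <- function(set) {
  d <- .inst_df(set)
  if (nrow(d) < 2) stop("IVW requires k >= 2 instruments", call. = FALSE)
  w <- 1 / d$sy^2
  beta <- sum(w * d$bx * d$by) / sum(w * d$bx^2)
  se_fixed <- 1 / sqrt(sum(w * d$bx^2))
  q <- sum(w * (d$by - beta * d$bx)^2)
  scale <- sqrt(max(1, q / (nrow(d) - 1)))
  new_mr_estimate("ivw_mre", beta, se_fixed * scale, nrow(d),
                  extras = list(Q = q, df = nrow(d) - 1L,
                                se_fixed = se_fixed, scale = scale))
}

# profile log-likelihood in theta: for fixed theta the per-variant true
# effects xi_j have the closed-form maximizer
# xi_j = (bx/sx^2 + theta*by/sy^2) / (1/sx^2 + theta^2/sy^2)
.profile_loglik <- function(theta, d) {
  xi <- (d$bx / d$sx^2 + theta * d$by / d$sy^2) /
    (1 / d$sx^2 + theta^2 / d$sy^2)
  -0.5 * sum((d$bx - xi)^2 / d$sx^2 + (d$by - theta * xi)^2 / d$sy^2)
}

#' Likelihood-based Mendelian-randomization estimator
#'
#' Maximum-likelihood fit of the bivariate-normal measurement model
#' `bx_j ~ N(xi_j, sx_j^2)`, `by_j ~ N(theta * xi_j, sy_j^2)` with zero
#' exposure-outcome correlation (non-overlapping samples). The per-variant
#' nuisance means `xi_j` are profiled out in closed form and `theta` is
#' found by one-dimensional optimization; the SE comes from the numerical
#' curvature of the profile log-likelihood at the maximum, with
#' normal-theory confidence limits.
#'
#' @param set an `instrument_set` (k >= 1).
#' @param theta_range search interval for `theta`.
#' @return an `mr_estimate` with the maximized log-likelihood in `extras`.
#' @export
likelihood_based <- function(set, theta_range = c(-5, 5)) {
  d <- .inst_df(set)
  if (nrow(d) < 1) stop("likelihood-based MR requires k >= 1", call. = FALSE)
  opt <- optimize(.profile_loglik, interval = theta_range, d = d,
                  maximum = TRUE, tol = 1e-10)
  theta <- opt$maximum
  if (min(abs(theta - theta_range)) < 1e-6) {
    stop("likelihood-based MR did not converge inside theta_range; ",
         sprintf("boundary estimate %.4f", theta), call. = FALSE)
  }
  h <- 1e-4 * max(1e-3, abs(theta))
  d2 <- (.profile_loglik(theta + h, d) - 2 * opt$objective +
           .profile_loglik(theta - h, d)) / h^2
  if (!is.finite(d2) || d2 >= 0) {
    stop("likelihood-based MR: non-concave profile likelihood at optimum",
         call. = FALSE)
  }
  new_mr_estimate("likelihood_based", theta, 1 / sqrt(-d2), nrow(d),
                  extras = list(loglik = opt$objective))
}

# weighted least squares of by on X with weights w; returns coef, cov
# (unscaled), and weighted RSS
.wls <- function(X, y, w) {
  A <- crossprod(X * w, X)
  b <- crossprod(X * w, y)
  cf <- solve(A, b)
  rss <- sum(w * (y - X %*% cf)^2)
  list(coef = drop(cf), cov = solve(A), rss = rss)
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome on exposure effects *with* an
#' unconstrained intercept (weights `1/sy^2`), after orienting every
#' instrument to `bx >= 0`. The slope estimates the causal effect; a
#' non-zero intercept indicates directional (unbalanced) horizontal
#' pleiotropy. Standard errors use the multiplicative random-effects scale
#' `sqrt(max(1, RSS/(k-2)))`; p-values use a t-distribution with `k - 2`
#' degrees of freedom. `extras` carries the intercept, its SE and p.
#'
#' @param set an `instrument_set` with at least 3 variants.
#' @return an `mr_estimate` (slope) with intercept diagnostics in `extras`.
#' @export
egger <- function(set) {
  d <- .inst_df(set)
  k <- nrow(d)
  if (k < 3) stop("MR-Egger requires k >= 3 instruments", call. = FALSE)
  flip <- d$bx < 0
  d$by[flip] <- -d$by[flip]; d$bx[flip] <- -d$bx[flip]
  w <- 1 / d$sy^2
  fit <- .wls(cbind(intercept = 1, bx = d$bx), d$by, w)
  scale2 <- max(1, fit$rss / (k - 2))
  ses <- sqrt(diag(fit$cov) * scale2)
  i_p <- 2 * pt(-abs(fit$coef[1] / ses[1]), df = k - 2)
  new_mr_estimate("egger", unname(fit$coef[2]), unname(ses[2]), k, df = k - 2,
                  extras = list(intercept = unname(fit$coef[1]),
                                intercept_se = unname(ses[1]),
                                intercept_p = unname(i_p),
                                rss = fit$rss))
}

# weighted median of values x with weights w, interpolated at cumulative
# weight 0.5 (percentile convention, ties by midpoint through ordering)
.weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  p <- cumsum(w) - w / 2
  if (p[1] >= 0.5) return(x[1])
  n <- length(x)
  if (p[n] <= 0.5) return(x[n])
  j <- max(which(p < 0.5))
  x[j] + (x[j + 1] - x[j]) * (0.5 - p[j]) / (p[j + 1] - p[j])
}

#' Weighted-median estimator
#'
#' The inverse-variance weighted median of the per-variant Wald ratios:
#' consistent when instruments carrying at least half the weight are valid.
#' Ratio SEs use the first-order delta method, weights `1/se(ratio)^2`, and
#' the median is interpolated at cumulative weight 0.5. The SE is a
#' parametric bootstrap (resampling `bx`, `by` from their SEs) with an
#' explicit seed.
#'
#' @param set an `instrument_set` with at least 3 variants.
#' @param n_boot bootstrap resamples.
#' @param seed integer seed for the bootstrap.
#' @return an `mr_estimate`.
#' @export
weighted_median <- function(set, n_boot = 1000L, seed = 1L) {
  d <- .inst_df(set)
  k <- nrow(d)
  if (k < 3) stop("weighted median requires k >= 3 instruments", call. = FALSE)
  ratio <- d$by / d$bx
  w <- (d$bx / d$sy)^2          # 1 / se(ratio)^2, first-order
  beta <- .weighted_median(ratio, w)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    bx <- rnorm(k, d$bx, d$sx); by <- rnorm(k, d$by, d$sy)
    .weighted_median(by / bx, (bx / d$sy)^2)
  }, numeric(1))
  new_mr_estimate("weighted_median", beta, sd(boots), k,
                  extras = list(n_boot = n_boot, seed = seed))
}

# normal-kernel density argmax of x with bandwidth h over a fine grid
.kde_argmax <- function(x, h, grid_n = 4096L) {
  g <- seq(min(x) - 3 * h, max(x) + 3 * h, length.out = grid_n)
  dens <- vapply(g, function(t) sum(dnorm((t - x) / h)), numeric(1))
  g[which.max(dens)]
}

#' Simple mode-based estimator
#'
#' The mode of the density of per-variant Wald ratios: consistent when the
#' largest group of instruments sharing the same ratio is valid (zero modal
#' pleiotropy). The density is a normal-kernel estimate over the unweighted
#' ratios with bandwidth `bandwidth_factor` times the modified Silverman
#' rule `0.9 * min(sd, mad) * k^(-1/5)`; the mode is located by fine-grid
#' search. SE by parametric bootstrap with an explicit seed.
#'
#' @param set an `instrument_set` with at least 3 variants.
#' @param bandwidth_factor multiplier on the rule-of-thumb bandwidth.
#' @param n_boot bootstrap resamples.
#' @param seed integer seed for the bootstrap.
#' @return an `mr_estimate` with the bandwidth used in `extras`.
#' @export
mode_based <- function(set, bandwidth_factor = 1, n_boot = 1000L, seed = 1L) {
  d <- .inst_df(set)
  k <- nrow(d)
  if (k < 3) stop("mode-based estimator requires k >= 3 instruments",
                  call. = FALSE)
  ratio <- d$by / d$bx
  bw_of <- function(r) {
    s <- min(sd(r), mad(r))
    if (s == 0) s <- max(sd(r), 1e-8)
    bandwidth_factor * 0.9 * s * length(r)^(-1 / 5)
  }
  h <- bw_of(ratio)
  beta <- .kde_argmax(ratio, h)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    bx <- rnorm(k, d$bx, d$sx); by <- rnorm(k, d$by, d$sy)
    r <- by / bx
    .kde_argmax(r, bw_of(r), grid_n = 512L)
  }, numeric(1))
  new_mr_estimate("mode_based", beta, sd(boots), k,
                  extras = list(bandwidth = h, n_boot = n_boot, seed = seed))
}
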