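#' Restricted cubic spline basis with three knots
#'
#' Harrell's truncated-power restricted cubic spline: piecewise cubic,
#' linear beyond the boundary knots. With three knots `t1 < t2 < t3` the
#' basis adds a single nonlinear term to the linear one,
#' `((x-t1)+^3 - (x-t2)+^3 (t3-t1)/(t3-t2) + (x-t3)+^3 (t2-t1)/(t3-t2)) / (t3-t1)^2`,
#' which is identically zero at and below the first knot.
#'
#' @param x numeric vector.
#' @param knots strictly increasing vector of 3 knot locations.
#' @return numeric vector, the nonlinear basis term.
#' @export
rcs_nonlinear_basis <- function(x, knots) {
  .check(length(knots) == 3 && all(diff(knots) > 0), "knots",
         "must be 3 strictly increasing values")
  t1 <- knots[1]; t2 <- knots[2]; t3 <- knots[3]
  pp3 <- function(u) pmax(u, 0)^3
  (pp3(x - t1) - pp3(x - t2) * (t3 - t1) / (t3 - t2) +
     pp3(x - t3) * (t2 - t1) / (t3 - t2)) / (t3 - t1)^2
}

#' Default three-knot placement at Harrell's percentiles
#'
#' @param x numeric vector of exposure values.
#' @param probs percentiles for the knots (default 10th, 50th, 90th).
#' @return numeric vector of 3 knots.
#' @export
spline_knots <- function(x, probs = c(0.10, 0.50, 0.90)) {
  kn <- unname(quantile(x, probs, type = 7))
  .check(all(diff(kn) > 0), "knots",
         "percentile knots are not strictly increasing (too few distinct values)")
  kn
}

#' Spline dose-response and nonlinearity test
#'
#' Fits the conditional logistic model with a three-knot restricted cubic
#' spline in standardized log-exposure (one linear plus one nonlinear
#' term), adjusting for `covariates`, and Wald-tests the nonlinear
#' coefficient. Also returns the predicted log-OR curve relative to a
#' reference exposure (the first knot, i.e. the 10th percentile, by
#' default).
#'
#' @param pairs standardized cohort (see [standardize_log_exposure()]).
#' @param knots 3 knots on the `log_exposure_z` scale; default Harrell's
#'   10th/50th/90th percentiles.
#' @param covariates adjustment covariates.
#' @param grid_n points in the emitted dose-response curve.
#' @return list with `fit` (the `clogit_result`), `wald_p_nonlinear`,
#'   `knots`, and `curve` (data frame: `log_exposure_z`, `log_or`,
#'   relative to the reference knot).
#' @export
spline_nonlinearity <- function(pairs, knots = NULL,
                                covariates = character(0), grid_n = 101L) {
  if (!"log_exposure_z" %in% names(pairs)) {
    stop("run standardize_log_exposure() first", call. = FALSE)
  }
  z <- pairs$log_exposure_z
  if (length(unique(z)) < 3) stop("need >= 3 distinct exposure values",
                                  call. = FALSE)
  if (is.null(knots)) knots <- spline_knots(z)
  pairs$.rcs_nl <- rcs_nonlinear_basis(z, knots)
  fit <- clogit_fit(pairs, covariates = c(".rcs_nl", covariates))
  nl <- fit$coefficients[fit$coefficients$term == ".rcs_nl", ]
  wald_p <- 2 * pnorm(-abs(nl$beta / nl$se))
  g <- seq(min(z), max(z), length.out = grid_n)
  b_lin <- fit$coefficients$beta[fit$coefficients$term == "exposure_z"]
  ref <- knots[1]
  log_or <- b_lin * (g - ref) +
    nl$beta * (rcs_nonlinear_basis(g, knots) - rcs_nonlinear_basis(ref, knots))
  list(fit = fit, wald_p_nonlinear = wald_p, knots = knots,
       curve = data.frame(log_exposure_z = g, log_or = log_or))
}

# shared stratified fit: per-stratum exposure coefficients
# (z * I(stratum == s) columns) plus common covariates; Wald test of
# coefficient equality across strata
.stratified_clogit <- function(pairs, stratum, covariates,
                               het_test = c("wald", "lr")) {
  het_test <- match.arg(het_test)
  lv <- sort(unique(stratum))
  if (length(lv) < 2) stop("modifier/stratum is constant", call. = FALSE)
  for (s in lv) {
    pairs[[paste0(".z_", s)]] <- pairs$log_exposure_z * (stratum == s)
  }
  zcols <- paste0(".z_", lv)
  # reuse the difference machinery with a dummy constant exposure term
  # removed: fit directly on the stratum-specific columns
  X <- .pair_differences(pairs, c(zcols, covariates))
  X <- X[, colnames(X) != "exposure_z", drop = FALSE]
  fit <- suppressWarnings(glm.fit(X, rep(1, nrow(X)), family = binomial(),
                                  intercept = FALSE))
  cf <- coef(fit)
  if (any(!is.finite(cf)) || any(abs(cf) > 15)) {
    stop("stratified conditional logistic fit did not converge", call. = FALSE)
  }
  p <- 1 / (1 + exp(-drop(X %*% cf)))
  V <- solve(crossprod(X * (p * (1 - p)), X))
  ses <- sqrt(diag(V))
  idx <- match(zcols, colnames(X))
  b <- cf[idx]; sb <- ses[idx]
  strata <- data.frame(
    stratum = lv, beta = unname(b), se = unname(sb),
    or_ = exp(unname(b)),
    ci_low = exp(unname(b) - Z95 * unname(sb)),
    ci_high = exp(unname(b) + Z95 * unname(sb)),
    pval = 2 * pnorm(-abs(unname(b) / unname(sb))),
    n_pairs = as.integer(table(factor(stratum, levels = lv))[lv] / 2),
    stringsAsFactors = FALSE
  )
  ns <- length(lv)
  C <- cbind(1, diag(-1, ns - 1))            # b1 - bs = 0 contrasts
  if (het_test == "wald") {
    cb <- drop(C %*% b)
    W <- drop(t(cb) %*% solve(C %*% V[idx, idx] %*% t(C)) %*% cb)
    p_het <- pchisq(W, df = ns - 1, lower.tail = FALSE)
  } else {
    ll_full <- sum(log(p))
    Xr <- cbind(exposure_z = rowSums(X[, idx, drop = FALSE]),
                X[, -idx, drop = FALSE])
    fr <- suppressWarnings(glm.fit(Xr, rep(1, nrow(Xr)), family = binomial(),
                                   intercept = FALSE))
    pr <- 1 / (1 + exp(-drop(Xr %*% coef(fr))))
    p_het <- pchisq(2 * (ll_full - sum(log(pr))), df = ns - 1,
                    lower.tail = FALSE)
  }
  list(strata = strata, p_heterogeneity = p_het)
}

#' Effect modification by a covariate
#'
#' Tests whether the exposure log-OR differs across strata of a modifier by
#' fitting stratum-specific exposure coefficients within the multivariable
#' conditional logistic model and Wald-testing their equality (equivalent
#' to testing the multiplicative interaction terms). Continuous modifiers
#' are dichotomized at their median by default (`cutpoint = "median"`);
#' categorical modifiers use their observed categories. The modifier must
#' be concordant within a pair (matching factors are; for discordant pairs,
#' e.g. genotype strata, only concordant pairs are analysed, mirroring the
#' usual stratified presentation) — discordant pairs are dropped with a
#' note in the result.
#'
#' @param pairs standardized cohort.
#' @param modifier covariate name.
#' @param cutpoint `"median"` (dichotomize a continuous modifier) or
#'   `"categories"` (use values as-is).
#' @param covariates adjustment covariates (the modifier itself is
#'   excluded automatically).
#' @return list with `strata` (per-stratum ORs), `p_heterogeneity`, and
#'   `n_pairs_dropped` (modifier-discordant pairs).
#' @export
interaction_test <- function(pairs, modifier, cutpoint = c("median", "categories"),
                             covariates = character(0)) {
  cutpoint <- match.arg(cutpoint)
  .check(modifier %in% names(pairs), "modifier", "not found in cohort")
  m <- pairs[[modifier]]
  if (is.numeric(m) && cutpoint == "median") {
    med <- median(m, na.rm = TRUE)
    m <- ifelse(m < med, "below_median", "at_or_above_median")
  } else {
    m <- as.character(m)
    m[is.na(m)] <- "missing"
  }
  if (length(unique(m)) < 2) stop("modifier is constant", call. = FALSE)
  # keep pairs with a concordant modifier value
  first <- tapply(m, pairs$pair_id, function(v) v[1])
  conc <- tapply(m, pairs$pair_id, function(v) length(unique(v)) == 1)
  keep_ids <- names(conc)[conc]
  dropped <- sum(!conc)
  sub <- pairs[as.character(pairs$pair_id) %in% keep_ids, , drop = FALSE]
  stratum <- unname(first[as.character(sub$pair_id)])
  out <- .stratified_clogit(sub, stratum, setdiff(covariates, modifier))
  out$n_pairs_dropped <- dropped
  out
}

#' Sub-site heterogeneity by competing risks
#'
#' Stratified conditional logistic model in which each case is compared
#' with its matched control and the exposure coefficient is indexed by the
#' case's tumour sub-site, with common covariate adjustment. Heterogeneity
#' of the site-specific log-ORs is tested by a Wald contrast (default) or
#' likelihood ratio. For `"colon_vs_rectum"`, overlapping colon cases count
#' as colon; for `"proximal_vs_distal"`, overlapping-colon and rectal pairs
#' are excluded.
#'
#' @param pairs standardized cohort with a `subsite` column (pair-level:
#'   the case's site).
#' @param grouping `"colon_vs_rectum"` or `"proximal_vs_distal"`.
#' @param covariates adjustment covariates.
#' @param het_test `"wald"` or `"lr"`.
#' @return list with `strata` (per-site ORs) and `p_heterogeneity`.
#' @export
subsite_heterogeneity <- function(pairs,
                                  grouping = c("colon_vs_rectum",
                                               "proximal_vs_distal"),
                                  covariates = character(0),
                                  het_test = c("wald", "lr")) {
  grouping <- match.arg(grouping)
  .check("subsite" %in% names(pairs), "pairs", "needs a subsite column")
  site <- as.character(pairs$subsite)
  if (grouping == "colon_vs_rectum") {
    grp <- ifelse(site %in% c("proximal", "distal", "overlapping_colon"),
                  "colon", "rectum")
    sub <- pairs
  } else {
    keep <- site %in% c("proximal", "distal")
    sub <- pairs[keep, , drop = FALSE]
    grp <- site[keep]
  }
  present <- unique(grp)
  if (length(present) < 2) {
    stop("need informative pairs in at least 2 sites", call. = FALSE)
  }
  .stratified_clogit(sub, grp, covariates, het_test = match.arg(het_test))
}

#' Liver-function exclusion filter
#'
#' Computes the BTR index (molar ratio of branched-chain amino acids to
#' tyrosine) and Fischer's ratio (BCAA to tyrosine plus phenylalanine) and
#' drops every pair in which either member falls below either threshold —
#' a screen for subclinical liver dysfunction, which both lowers these
#' ratios and raises bilirubin.
#'
#' @param pairs cohort with `bcaa`, `tyrosine`, `phenylalanine` (umol/L).
#' @param btr_min minimum BTR index.
#' @param fischer_min minimum Fischer's ratio.
#' @return list with `kept` (the filtered cohort, with `btr` and `fischer`
#'   columns added) and `excluded_pairs` (pair ids with the triggering
#'   member's ratios).
#' @export
liver_exclusion <- function(pairs, btr_min = 4, fischer_min = 2) {
  need <- c("bcaa", "tyrosine", "phenylalanine")
  .check(all(need %in% names(pairs)), "pairs", "needs the liver amino-acid panel")
  denom1 <- pairs$tyrosine
  denom2 <- pairs$tyrosine + pairs$phenylalanine
  bad <- which(denom1 <= 0 | denom2 <= 0)
  if (length(bad)) {
    stop(sprintf("zero/negative denominator in record(s): %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  pairs$btr <- pairs$bcaa / denom1
  pairs$fischer <- pairs$bcaa / denom2
  flag <- pairs$btr < btr_min | pairs$fischer < fischer_min
  bad_ids <- unique(pairs$pair_id[flag])
  keep <- !(pairs$pair_id %in% bad_ids)
  list(kept = pairs[keep, , drop = FALSE],
       excluded_pairs = pairs[pairs$pair_id %in% bad_ids & flag,
                              c("pair_id", "case", "btr", "fischer")])
}

#' Validate the lead variant against measured exposure
#'
#' Ordinary least-squares regression of measured log-exposure on the allele
#' dose (0/1/2) of the exposure-increasing allele among controls — the
#' serological-arm check that the genetic instrument predicts the measured
#' biomarker.
#'
#' @param controls data frame of control subjects with `lead_genotype` and
#'   positive `exposure`.
#' @return list with `slope`, `se`, `r2`, `pval`, `n`.
#' @export
genotype_exposure_check <- function(controls) {
  .check(nrow(controls) >= 3, "controls", "need at least 3 subjects")
  g <- controls$lead_genotype
  if (length(unique(g)) < 2) stop("constant genotype: regression undefined",
                                  call. = FALSE)
  y <- log(controls$exposure)
  fit <- lm(y ~ g)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), se = sm$coefficients[2, 2],
       r2 = sm$r.squared, pval = sm$coefficients[2, 4], n = nrow(controls))
}
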