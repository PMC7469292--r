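#' Variance in a standardized trait explained by one variant
#'
#' For a standardized (unit-variance) trait, a variant with per-allele
#' effect `beta_sd` (SD units) and minor allele frequency `maf` explains
#' `2 * maf * (1 - maf) * beta_sd^2` of phenotypic variance under
#' Hardy-Weinberg. Symmetric in `maf` vs `1 - maf`, so either allele's
#' frequency may be supplied.
#'
#' @param beta_sd per-allele effect in SD units.
#' @param maf allele frequency in (0, 1).
#' @return fraction of variance explained.
#' @export
variance_explained <- function(beta_sd, maf) {
  .check(all(maf > 0 & maf < 1), "maf", "must lie in (0, 1)")
  2 * maf * (1 - maf) * beta_sd^2
}

#' Instrument-strength F-statistic
#'
#' `F = ((n - k - 1) / k) * (R2 / (1 - R2))`, where `R2` is the variance
#' explained by the instrument, `n` the exposure-GWAS sample size and `k`
#' the number of variants. Values above ~10 indicate negligible
#' weak-instrument bias.
#'
#' @param r2 variance explained, in [0, 1).
#' @param n exposure sample size.
#' @param k number of variants.
#' @return the F-statistic.
#' @export
f_statistic <- function(r2, n, k) {
  .check(r2 >= 0 && r2 < 1, "r2", "must lie in [0, 1)")
  .check(n > k + 1, "n", "must exceed k + 1")
  ((n - k - 1) / k) * (r2 / (1 - r2))
}

#' Genotyping quality-control filter for summary statistics
#'
#' Removes variants failing any of: call rate below `call_rate_min`,
#' Hardy-Weinberg p-value (in controls) below `hwe_p_min`, or minor allele
#' frequency at or below `maf_min`. Each removed variant carries its first
#' failing reason, checked in that order. Variants lacking an optional
#' `call_rate` or `hwe_p` column/value pass that check.
#'
#' @param snps data frame of summary statistics (needs `snp`, `eaf`;
#'   optionally `call_rate`, `hwe_p`).
#' @param call_rate_min minimum call rate (default 0.98, the stricter of
#'   the source consortia's thresholds).
#' @param hwe_p_min minimum Hardy-Weinberg p (default 1e-4).
#' @param maf_min MAF threshold; variants with MAF <= this are removed
#'   (default 0.01).
#' @return list with `kept` (input order preserved) and `removed` (with a
#'   `reason` column).
#' @export
qc_filter <- function(snps, call_rate_min = 0.98, hwe_p_min = 1e-4,
                      maf_min = 0.01) {
  .check(call_rate_min > 0 && call_rate_min < 1, "call_rate_min", "must lie in (0,1)")
  .check(hwe_p_min > 0 && hwe_p_min < 1, "hwe_p_min", "must lie in (0,1)")
  .check(maf_min > 0 && maf_min < 1, "maf_min", "must lie in (0,1)")
  n <- nrow(snps)
  if (n == 0) {
    return(list(kept = snps, removed = cbind(snps, reason = character(0))))
  }
  get_opt <- function(col) {
    if (col %in% names(snps)) snps[[col]] else rep(NA_real_, n)
  }
  cr <- get_opt("call_rate"); hw <- get_opt("hwe_p")
  maf <- pmin(snps$eaf, 1 - snps$eaf)
  reason <- rep(NA_character_, n)
  reason[is.na(reason) & !is.na(cr) & cr < call_rate_min] <- "call_rate"
  reason[is.na(reason) & !is.na(hw) & hw < hwe_p_min] <- "hwe"
  reason[is.na(reason) & maf <= maf_min] <- "low_maf"
  removed <- snps[!is.na(reason), , drop = FALSE]
  if (nrow(removed)) removed$reason <- reason[!is.na(reason)]
  else removed <- cbind(removed, data.frame(reason = character(0)))
  list(kept = snps[is.na(reason), , drop = FALSE], removed = removed)
}

.is_palindromic <- function(a1, a2) {
  p <- paste0(a1, a2)
  p %in% c("AT", "TA", "CG", "GC")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns outcome effects to the exposure's effect allele: where the outcome
#' effect allele matches the exposure's other allele (and vice versa) the
#' outcome beta is negated and its frequency flipped. Strand-ambiguous
#' (palindromic A/T, C/G) variants are dropped or replaced by a supplied
#' proxy in LD R2 > 0.8, per `ambiguous_policy`; allele-frequency-based
#' rescue is deliberately not attempted. Finally each instrument is
#' oriented to the exposure-increasing allele (all `bx >= 0`) — estimates
#' are invariant to this, and scatter plots get a positive x-axis.
#'
#' @param exposure,outcome summary-statistic data frames in the package
#'   dialect (see [gen_two_sample_gwas()]).
#' @param ambiguous_policy `"drop"` or `"proxy"`.
#' @param proxy_map for `"proxy"`: a data frame with columns `snp`, `proxy`,
#'   `ld_r2`; a substitution is made only when `ld_r2 > 0.8` and the proxy
#'   is present (non-palindromic) in both tables.
#' @return an `instrument_set`: list with `instruments` (data frame of
#'   `snp_id`, `bx`, `sx`, `by`, `sy`, `eaf`, `aligned_allele`,
#'   `provenance`), `report` (per input variant: provenance/reason),
#'   `r2_total`, `f_statistic`, `exposure_n`, `k`.
#' @export
harmonize <- function(exposure, outcome, ambiguous_policy = c("drop", "proxy"),
                      proxy_map = NULL) {
  ambiguous_policy <- match.arg(ambiguous_policy)
  .check(!anyDuplicated(exposure$snp), "exposure", "snp ids must be unique")
  .check(!anyDuplicated(outcome$snp), "outcome", "snp ids must be unique")
  if (ambiguous_policy == "proxy" && is.null(proxy_map)) {
    stop("ambiguous_policy = \"proxy\" requires a proxy_map", call. = FALSE)
  }
  out_idx <- setNames(seq_len(nrow(outcome)), outcome$snp)
  exp_idx <- setNames(seq_len(nrow(exposure)), exposure$snp)

  rows <- vector("list", nrow(exposure))
  report <- data.frame(snp = exposure$snp, provenance = NA_character_,
                       reason = NA_character_, stringsAsFactors = FALSE)

  align_one <- function(e, provenance) {
    o_i <- out_idx[[e$snp]]
    if (is.null(o_i)) return(list(reason = "missing_outcome"))
    o <- outcome[o_i, ]
    by <- o$beta; eaf_o <- o$eaf
    if (identical(o$effect_allele, e$effect_allele) &&
        identical(o$other_allele, e$other_allele)) {
      # direct
    } else if (identical(o$effect_allele, e$other_allele) &&
               identical(o$other_allele, e$effect_allele)) {
      by <- -by; eaf_o <- 1 - eaf_o
      if (provenance == "direct") provenance <- "allele-flipped"
    } else {
      return(list(reason = "allele_mismatch"))
    }
    bx <- e$beta; eaf <- e$eaf; allele <- e$effect_allele
    if (bx < 0) {  # orient to the exposure-increasing allele
      bx <- -bx; by <- -by; eaf <- 1 - eaf; allele <- e$other_allele
    }
    list(row = data.frame(snp_id = e$snp, bx = bx, sx = e$se, by = by,
                          sy = o$se, eaf = eaf, aligned_allele = allele,
                          provenance = provenance, stringsAsFactors = FALSE))
  }

  for (i in seq_len(nrow(exposure))) {
    e <- exposure[i, ]
    prov <- "direct"
    if (.is_palindromic(e$effect_allele, e$other_allele)) {
      if (ambiguous_policy == "drop") {
        report$provenance[i] <- "dropped"; report$reason[i] <- "ambiguous_strand"
        next
      }
      pm <- proxy_map[proxy_map$snp == e$snp, , drop = FALSE]
      ok <- nrow(pm) == 1 && pm$ld_r2 > 0.8 &&
        pm$proxy %in% names(exp_idx) && pm$proxy %in% names(out_idx)
      if (!ok) {
        report$provenance[i] <- "dropped"; report$reason[i] <- "ambiguous_strand"
        next
      }
      e <- exposure[exp_idx[[pm$proxy]], ]
      if (.is_palindromic(e$effect_allele, e$other_allele)) {
        report$provenance[i] <- "dropped"; report$reason[i] <- "ambiguous_strand"
        next
      }
      prov <- "proxy-substituted"
    }
    res <- align_one(e, prov)
    if (!is.null(res$reason)) {
      report$provenance[i] <- "dropped"; report$reason[i] <- res$reason
    } else {
      rows[[i]] <- res$row
      report$provenance[i] <- res$row$provenance
    }
  }

  inst <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(inst)) {
    inst <- data.frame(snp_id = character(0), bx = numeric(0), sx = numeric(0),
                       by = numeric(0), sy = numeric(0), eaf = numeric(0),
                       aligned_allele = character(0),
                       provenance = character(0), stringsAsFactors = FALSE)
  }
  inst <- inst[!duplicated(inst$snp_id), , drop = FALSE]
  rownames(inst) <- NULL
  exposure_n <- if ("n" %in% names(exposure) && nrow(exposure))
    max(exposure$n) else NA_integer_
  new_instrument_set(inst, exposure_n, report = report)
}

#' Construct an instrument set
#'
#' Internal constructor shared by [harmonize()] and [leave_out()]; computes
#' `r2_total` as the sum of per-variant [variance_explained()] and the
#' instrument [f_statistic()].
#'
#' @param instruments harmonized instrument data frame.
#' @param exposure_n exposure-GWAS sample size.
#' @param report optional harmonization report.
#' @return an `instrument_set`.
#' @export
new_instrument_set <- function(instruments, exposure_n, report = NULL) {
  k <- nrow(instruments)
  r2 <- if (k) sum(variance_explained(instruments$bx, instruments$eaf)) else 0
  f <- if (k && !is.na(exposure_n) && exposure_n > k + 1)
    f_statistic(min(r2, 1 - 1e-12), exposure_n, k) else NA_real_
  structure(list(instruments = instruments, report = report,
                 r2_total = r2, f_statistic = f,
                 exposure_n = exposure_n, k = k),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("instrument_set: %d variants, R2 = %.4f, F = %.1f (n = %s)\n",
              x$k, x$r2_total, x$f_statistic, format(x$exposure_n)))
  invisible(x)
}

#' Remove one variant from an instrument set
#'
#' Returns the set without the named variant, with `k`, `r2_total` and
#' `f_statistic` recomputed — used for leave-one-out sensitivity analyses
#' and for splitting the lead variant from the rest of the instrument.
#'
#' @param set an `instrument_set`.
#' @param snp_id variant to remove (must be present).
#' @return an `instrument_set` with `k - 1` variants.
#' @export
leave_out <- function(set, snp_id) {
  stopifnot(inherits(set, "instrument_set"))
  keep <- set$instruments$snp_id != snp_id
  if (all(keep)) stop(sprintf("snp '%s' not in instrument set", snp_id),
                      call. = FALSE)
  new_instrument_set(set$instruments[keep, , drop = FALSE], set$exposure_n,
                     report = set$report)
}

#' Approximate power of a binary-outcome Mendelian-randomization study
#'
#' Normal-approximation power for detecting a causal odds ratio `or_alt`
#' per 1-SD of exposure with an instrument explaining `r2` of exposure
#' variance:
#' `power = pnorm(sqrt(N * r2 * phi * (1 - phi)) * |log(or_alt)| - z_(1-alpha/2))`,
#' with `N` the total outcome sample size and `phi` the case fraction.
#' This is the conventional first-order approximation; its result at any
#' given design is what the formula yields, with no claim to replicate any
#' externally computed power figure.
#'
#' @param n_cases,n_controls outcome counts.
#' @param r2 instrument variance explained, in (0, 1).
#' @param or_alt alternative-hypothesis odds ratio (> 0).
#' @param alpha two-sided significance level.
#' @return power as a fraction.
#' @export
mr_power_binary <- function(n_cases, n_controls, r2, or_alt, alpha = 0.05) {
  .check(n_cases > 0 && n_controls > 0, "n_cases", "counts must be positive")
  .check(r2 > 0 && r2 < 1, "r2", "must lie in (0, 1)")
  .check(or_alt > 0, "or_alt", "must be positive")
  .check(alpha > 0 && alpha < 1, "alpha", "must lie in (0, 1)")
  n <- n_cases + n_controls
  phi <- n_cases / n
  pnorm(sqrt(n * r2 * phi * (1 - phi)) * abs(log(or_alt)) - qnorm(1 - alpha / 2))
}
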