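#' Configuration for a two-sample GWAS summary-statistic simulation
#'
#' Describes a genetic instrument of `n_snps` independent variants for a
#' standardized exposure, with the variance-explained structure of the
#' bilirubin instrument: one lead variant carrying `lead_r2` (default 16.9%)
#' and the remaining variants jointly carrying `other_r2_total` (default
#' 3.1%, so 20.0% in total). Outcome (log-OR) effects are `theta * true
#' exposure effect`, plus optional directional pleiotropy and planted
#' outlier offsets. Exposure and outcome noise are independent, emulating
#' non-overlapping discovery and outcome samples.
#'
#' Default sample sizes are the study's: exposure n = 317,639; outcome
#' 28,270 cases / 22,204 controls (the male stratum; pass the female counts
#' 24,568 / 23,736 to emulate that stratum).
#'
#' @param n_snps number of instrument variants (default 115).
#' @param lead_r2 exposure variance explained by variant 1 (default 0.169).
#' @param other_r2_total exposure variance explained jointly by the other
#'   variants (default 0.031).
#' @param exposure_n exposure-GWAS sample size.
#' @param outcome_cases,outcome_controls outcome case/control counts.
#' @param causal_logor_per_sd planted causal log-OR per 1-SD exposure.
#' @param pleiotropy_mean,pleiotropy_sd mean/SD of per-variant direct
#'   (pleiotropic) effects on the outcome log-OR scale; defaults 0, 0.
#' @param n_outliers number of variants (chosen from the non-lead set) given
#'   an additional outcome offset.
#' @param outlier_offset the log-OR offset added to each outlier.
#' @param maf_range interval within (0, 0.5] from which MAFs are drawn
#'   uniformly.
#' @param seed integer seed.
#' @return a `gwas_config` list.
#' @export
gwas_config <- function(n_snps = 115L,
                        lead_r2 = 0.169,
                        other_r2_total = 0.031,
                        exposure_n = 317639L,
                        outcome_cases = 28270L,
                        outcome_controls = 22204L,
                        causal_logor_per_sd = 0,
                        pleiotropy_mean = 0,
                        pleiotropy_sd = 0,
                        n_outliers = 0L,
                        outlier_offset = 0,
                        maf_range = c(0.05, 0.5),
                        seed = 1L) {
  .check(is.numeric(n_snps) && n_snps >= 1, "n_snps", "must be a count >= 1")
  .check(lead_r2 >= 0 && other_r2_total >= 0 && lead_r2 + other_r2_total < 1,
         "lead_r2", "lead_r2 + other_r2_total must lie in [0, 1)")
  .check(exposure_n > 0 && outcome_cases > 0 && outcome_controls > 0,
         "exposure_n", "all sample sizes must be positive")
  .check(length(maf_range) == 2 && maf_range[1] > 0 && maf_range[2] <= 0.5 &&
           maf_range[1] <= maf_range[2],
         "maf_range", "must be an interval within (0, 0.5]")
  .check(n_outliers >= 0 && n_outliers < n_snps, "n_outliers",
         "must be a count below n_snps")
  structure(list(
    n_snps = as.integer(n_snps), lead_r2 = lead_r2,
    other_r2_total = other_r2_total, exposure_n = as.numeric(exposure_n),
    outcome_cases = as.numeric(outcome_cases),
    outcome_controls = as.numeric(outcome_controls),
    causal_logor_per_sd = causal_logor_per_sd,
    pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
    n_outliers = as.integer(n_outliers), outlier_offset = outlier_offset,
    maf_range = maf_range, seed = as.integer(seed)
  ), class = "gwas_config")
}

#' Simulate two-sample GWAS summary statistics
#'
#' True per-variant exposure effects are drawn and rescaled so that the
#' realized variance explained, `sum(2*maf*(1-maf)*beta_true^2)`, equals
#' `lead_r2` for variant 1 and `other_r2_total` over the rest *exactly*.
#' Observed exposure effects add noise with the standard first-order SE for
#' a standardized trait, `1/sqrt(2*maf*(1-maf)*n)`; outcome effects are
#' `theta * beta_true + pleiotropy + outlier offsets` plus noise with
#' `1/sqrt(2*maf*(1-maf) * n_cases*n_controls/n)`. The two noise streams are
#' independent (non-overlapping samples). All alleles are emitted
#' non-palindromic (A/G) so harmonization keeps every variant by default.
#'
#' @param config a [gwas_config()].
#' @return a list with elements `exposure` and `outcome`, each a data frame
#'   in the package's summary-statistic dialect (`snp`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pval`, and `n` or
#'   `n_cases`/`n_controls`), plus `truth` (per-variant true effects, the
#'   planted theta, pleiotropy and outlier flags) for validation.
#' @export
gen_two_sample_gwas <- function(config) {
  stopifnot(inherits(config, "gwas_config"))
  set.seed(config$seed)
  k <- config$n_snps
  maf <- runif(k, config$maf_range[1], config$maf_range[2])
  het <- 2 * maf * (1 - maf)

  beta_true <- numeric(k)
  beta_true[1] <- sqrt(config$lead_r2 / het[1])
  if (k > 1) {
    raw <- abs(rnorm(k - 1, 0, 1)) + 0.1    # positive raw effect sizes
    v <- het[-1] * raw^2
    beta_true[-1] <- if (config$other_r2_total > 0)
      raw * sqrt(config$other_r2_total / sum(v)) else 0
  }

  se_x <- 1 / sqrt(het * config$exposure_n)
  n_out <- config$outcome_cases + config$outcome_controls
  se_y <- 1 / sqrt(het * config$outcome_cases * config$outcome_controls / n_out)

  pleio <- if (config$pleiotropy_sd > 0 || config$pleiotropy_mean != 0)
    rnorm(k, config$pleiotropy_mean, config$pleiotropy_sd) else numeric(k)
  outlier <- rep(FALSE, k)
  if (config$n_outliers > 0) {
    idx <- if (k > config$n_outliers + 1)
      sample(2:k, config$n_outliers) else seq_len(config$n_outliers)
    outlier[idx] <- TRUE
    pleio[idx] <- pleio[idx] + config$outlier_offset
  }

  bx <- beta_true + rnorm(k, 0, se_x)
  by <- config$causal_logor_per_sd * beta_true + pleio + rnorm(k, 0, se_y)

  snp <- sprintf("rs%06d", seq_len(k))
  exposure <- data.frame(
    snp = snp, effect_allele = "A", other_allele = "G", eaf = maf,
    beta = bx, se = se_x, pval = 2 * pnorm(-abs(bx / se_x)),
    n = config$exposure_n, stringsAsFactors = FALSE
  )
  outcome <- data.frame(
    snp = snp, effect_allele = "A", other_allele = "G", eaf = maf,
    beta = by, se = se_y, pval = 2 * pnorm(-abs(by / se_y)),
    n_cases = config$outcome_cases, n_controls = config$outcome_controls,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(snp = snp, maf = maf, beta_true = beta_true,
                      pleiotropy = pleio, outlier = outlier,
                      stringsAsFactors = FALSE)
  list(exposure = exposure, outcome = outcome, truth = truth,
       theta = config$causal_logor_per_sd, seed = config$seed)
}

#' Write / read summary statistics as tab-separated text
#'
#' The dialect is a plain TSV with header columns `snp`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pval`, and `n` (exposure) or
#' `n_cases`, `n_controls` (outcome); `#`-prefixed comment lines carry the
#' generating seed.
#'
#' @param stats a summary-statistic data frame.
#' @param path file path.
#' @param seed optional seed to record in the header.
#' @return `path`, invisibly (writer); the data frame (reader).
#' @export
write_gwas_tsv <- function(stats, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# bilimr GWAS summary statistics",
               sprintf("# seed: %s", if (is.null(seed)) "NA" else seed)), con)
  write.table(stats, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gwas_tsv
#' @export
read_gwas_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
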