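# build an instrument_set directly from effect vectors (skipping harmonize)
make_set <- function(bx, by, sy, sx = rep(1e-3, length(bx)),
                     eaf = rep(0.3, length(bx)), exposure_n = 1e5L) {
  k <- length(bx)
  inst <- data.frame(
    snp_id = sprintf("rs%03d", seq_len(k)),
    bx = bx, sx = sx, by = by, sy = sy, eaf = eaf,
    aligned_allele = rep("A", k), provenance = rep("direct", k),
    stringsAsFactors = FALSE
  )
  new_instrument_set(inst, exposure_n)
}

# small summary-statistic table in the package dialect
make_sumstats <- function(snp, ea, oa, eaf, beta, se, n = 1e5L) {
  data.frame(snp = snp, effect_allele = ea, other_allele = oa, eaf = eaf,
             beta = beta, se = se, pval = 2 * pnorm(-abs(beta / se)), n = n,
             stringsAsFactors = FALSE)
}

# quick standardized cohort
make_cohort <- function(n_pairs, sex = "male", theta = 0, seed = 1, ...) {
  cc <- cohort_config(n_pairs = n_pairs, sex = sex,
                      causal_logor_per_sd = theta, seed = seed, ...)
  standardize_log_exposure(gen_matched_cohort(cc))
}
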