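test_that("variance_explained evaluates 2pq beta^2 and is symmetric in maf", {
  expect_equal(variance_explained(0, 0.3), 0)
  expect_equal(variance_explained(0.5, 0.5), 0.125)
  expect_equal(variance_explained(0.4, 0.2), variance_explained(-0.4, 0.8))
  expect_error(variance_explained(0.1, 1.2), "maf")
})

test_that("f_statistic matches the closed form and its monotonicities", {
  expect_equal(f_statistic(0.031, 317639, 114), 89.1, tolerance = 0.001)
  expect_equal(f_statistic(0, 1000, 10), 0)
  expect_equal(f_statistic(0.5, 103, 2), 50)
  expect_error(f_statistic(0.1, 10, 9), "n")
  # increasing in r2, decreasing in k at fixed n
  r2s <- seq(0.01, 0.5, by = 0.01)
  expect_true(all(diff(vapply(r2s, f_statistic, numeric(1),
                              n = 1e4, k = 10)) > 0))
  ks <- 2:50
  expect_true(all(diff(vapply(ks, function(k) f_statistic(0.1, 1e4, k),
                              numeric(1))) < 0))
})

test_that("qc_filter applies thresholds with first-failure reasons and partitions input", {
  snps <- make_sumstats(sprintf("rs%d", 1:5), "A", "G",
                        eaf = c(0.3, 0.3, 0.3, 0.005, 0.3),
                        beta = 0.1, se = 0.01)
  snps$call_rate <- c(0.99, 0.97, 0.99, 0.99, 0.99)
  snps$hwe_p <- c(0.5, 0.5, 5e-5, 0.5, 0.5)
  out <- qc_filter(snps, 0.98, 1e-4, 0.01)
  expect_equal(nrow(out$kept), 2L)
  expect_equal(out$removed$snp, c("rs2", "rs3", "rs4"))
  expect_equal(out$removed$reason, c("call_rate", "hwe", "low_maf"))
  # exact partition
  expect_setequal(c(out$kept$snp, out$removed$snp), snps$snp)

  empty <- qc_filter(snps[0, ])
  expect_equal(nrow(empty$kept), 0L)
  expect_equal(nrow(empty$removed), 0L)

  all_pass <- qc_filter(make_sumstats("rs9", "A", "G", 0.4, 0.1, 0.01))
  expect_equal(all_pass$kept$snp, "rs9")
  expect_equal(nrow(all_pass$removed), 0L)
})

test_that("harmonize flips alleles, orients bx >= 0, and drops mismatches", {
  exposure <- make_sumstats(c("rs1", "rs2", "rs3"), c("A", "A", "A"),
                            c("G", "G", "G"), c(0.3, 0.4, 0.2),
                            beta = c(0.1, -0.2, 0.15), se = 0.01)
  outcome <- make_sumstats(c("rs1", "rs2", "rs3"),
                           c("G", "A", "C"), c("A", "G", "T"),
                           c(0.7, 0.4, 0.2),
                           beta = c(0.05, 0.03, 0.02), se = 0.02)
  set <- harmonize(exposure, outcome)
  d <- set$instruments
  # rs1: outcome on the other allele -> by negated
  expect_equal(d$by[d$snp_id == "rs1"], -0.05)
  expect_equal(d$provenance[d$snp_id == "rs1"], "allele-flipped")
  # rs2: exposure beta negative -> oriented, by flips sign too
  expect_equal(d$bx[d$snp_id == "rs2"], 0.2)
  expect_equal(d$by[d$snp_id == "rs2"], -0.03)
  expect_equal(d$aligned_allele[d$snp_id == "rs2"], "G")
  # rs3: unresolvable alleles
  expect_false("rs3" %in% d$snp_id)
  expect_equal(set$report$reason[set$report$snp == "rs3"], "allele_mismatch")
  expect_true(all(d$bx >= 0))
})

test_that("palindromic variants follow the drop-or-proxy policy", {
  exposure <- make_sumstats(c("rs1", "rs2"), c("A", "C"), c("T", "G"),
                            c(0.3, 0.2), beta = c(0.1, 0.2), se = 0.01)
  outcome <- make_sumstats(c("rs1", "rs2"), c("A", "C"), c("T", "G"),
                           c(0.3, 0.2), beta = c(0.05, 0.1), se = 0.02)
  dropped <- harmonize(exposure, outcome, ambiguous_policy = "drop")
  expect_equal(dropped$k, 0L)
  expect_true(all(dropped$report$reason == "ambiguous_strand"))

  expect_error(harmonize(exposure, outcome, ambiguous_policy = "proxy"),
               "proxy_map")

  exposure2 <- rbind(exposure,
                     make_sumstats("rs1_proxy", "A", "G", 0.31, 0.11, 0.01))
  outcome2 <- rbind(outcome,
                    make_sumstats("rs1_proxy", "A", "G", 0.31, 0.06, 0.02))
  pm <- data.frame(snp = c("rs1", "rs2"), proxy = c("rs1_proxy", "none"),
                   ld_r2 = c(0.95, 0.95), stringsAsFactors = FALSE)
  prox <- harmonize(exposure2, outcome2, ambiguous_policy = "proxy",
                    proxy_map = pm)
  expect_true("rs1_proxy" %in% prox$instruments$snp_id)
  expect_equal(prox$report$provenance[prox$report$snp == "rs1"],
               "proxy-substituted")
  expect_equal(prox$report$reason[prox$report$snp == "rs2"],
               "ambiguous_strand")
  # low-LD proxies are refused
  pm$ld_r2 <- 0.5
  low <- harmonize(exposure2, outcome2, ambiguous_policy = "proxy",
                   proxy_map = pm)
  expect_equal(low$report$reason[low$report$snp == "rs1"], "ambiguous_strand")
})

test_that("harmonization is idempotent and invariant to flipping both tables", {
  gw <- gen_two_sample_gwas(gwas_config(n_snps = 20, seed = 13,
                                        causal_logor_per_sd = 0.1))
  set1 <- harmonize(gw$exposure, gw$outcome)
  # re-express the output as inputs
  d <- set1$instruments
  oth <- ifelse(d$aligned_allele == "A", "G", "A")
  re_exp <- make_sumstats(d$snp_id, d$aligned_allele, oth, d$eaf, d$bx, d$sx)
  re_out <- make_sumstats(d$snp_id, d$aligned_allele, oth, d$eaf, d$by, d$sy)
  set2 <- harmonize(re_exp, re_out)
  expect_equal(set2$instruments$bx, d$bx, tolerance = 1e-12)
  expect_equal(set2$instruments$by, d$by, tolerance = 1e-12)
  expect_equal(set2$r2_total, set1$r2_total, tolerance = 1e-12)

  # flipping the allele labels in both tables leaves bx*by products intact
  flip <- function(s) {
    tmp <- s$effect_allele; s$effect_allele <- s$other_allele
    s$other_allele <- tmp; s$eaf <- 1 - s$eaf; s$beta <- -s$beta
    s
  }
  set3 <- harmonize(flip(gw$exposure), flip(gw$outcome))
  expect_equal(set3$instruments$bx * set3$instruments$by,
               d$bx * d$by, tolerance = 1e-12)
})

test_that("instrument-set r2 equals the sum of per-variant variance explained", {
  gw <- gen_two_sample_gwas(gwas_config(n_snps = 30, seed = 17))
  set <- harmonize(gw$exposure, gw$outcome)
  expect_equal(set$r2_total,
               sum(variance_explained(set$instruments$bx,
                                      set$instruments$eaf)),
               tolerance = 1e-12)
  expect_equal(set$f_statistic,
               f_statistic(set$r2_total, set$exposure_n, set$k),
               tolerance = 1e-12)
})

test_that("leave_out removes one variant, recomputes diagnostics, and round-trips", {
  gw <- gen_two_sample_gwas(gwas_config(seed = 23))
  set <- harmonize(gw$exposure, gw$outcome)
  rest <- leave_out(set, "rs000001")
  expect_equal(rest$k, 114L)
  expect_equal(rest$r2_total, 0.031, tolerance = 0.05)
  expect_equal(rest$f_statistic,
               f_statistic(rest$r2_total, 317639, 114), tolerance = 1e-12)
  expect_error(leave_out(set, "rs999999"), "not in instrument set")
  # re-adding the removed row restores the set (order-insensitive)
  readd <- rbind(rest$instruments,
                 set$instruments[set$instruments$snp_id == "rs000001", ])
  set2 <- new_instrument_set(readd, set$exposure_n)
  expect_equal(set2$r2_total, set$r2_total, tolerance = 1e-12)
  expect_setequal(set2$instruments$snp_id, set$instruments$snp_id)
})

test_that("mr_power_binary matches the formula and is monotone", {
  # null alternative: two-sided type-I tail
  expect_equal(mr_power_binary(1e4, 1e4, 0.2, 1, alpha = 0.05),
               pnorm(-qnorm(0.975)), tolerance = 1e-12)
  expect_equal(mr_power_binary(24568, 23736, 0.20, 1.065, 0.05),
               0.872, tolerance = 0.001)
  ors <- seq(1.01, 1.5, by = 0.01)
  pw <- vapply(ors, function(o) mr_power_binary(1e4, 1e4, 0.1, o), numeric(1))
  expect_true(all(diff(pw) > 0))
  r2s <- seq(0.01, 0.5, by = 0.01)
  pw2 <- vapply(r2s, function(r) mr_power_binary(1e4, 1e4, r, 1.1), numeric(1))
  expect_true(all(diff(pw2) > 0))
})
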