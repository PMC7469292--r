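# bilimr

Sex-stratified, dual-design analysis of circulating bilirubin and
colorectal cancer (CRC) risk, as an R package plus a scripted workflow.

Bilirubin is an endogenous antioxidant, and mild unconjugated
hyperbilirubinemia (Gilbert's syndrome, tagged by a *UGT1A1* promoter
polymorphism) has been proposed to protect against CRC. `bilimr`
implements the two designs used to test this:

* **Serological arm** — a nested case-control study of 1:1
  incidence-density-matched pairs. Conditional logistic regression of
  case status on standardized log unconjugated bilirubin (log-UCB) via
  the exact pair-difference likelihood; three-knot restricted cubic
  spline dose-response with a Wald nonlinearity test; effect
  modification (age, genotype, smoking, ...) by stratum-specific
  coefficients; competing-risks sub-site heterogeneity (colon vs rectum,
  proximal vs distal); BTR/Fischer liver-function exclusion filters; and
  validation of the lead variant against measured bilirubin in controls.
* **Mendelian-randomization arm** — two-sample MR with a 115-variant
  total-bilirubin instrument (lead *UGT1A1* variant: 16.9% of exposure
  variance; the other 114: 3.1%). Summary-statistic QC and
  harmonization, instrument strength (per-variant `2p(1-p)β²`;
  `F = ((n-k-1)/k)·(R²/(1-R²))`), power approximation, and the estimator
  suite: per-variant Wald ratios, likelihood-based MR (profile
  likelihood), IVW with multiplicative random effects, MR-Egger,
  weighted median, mode-based estimate, MR-PRESSO global/outlier/
  distortion tests, leave-one-out, and fixed-effect between-sex
  heterogeneity (Cochran Q, I²).

The real cohort and consortium data are access-controlled, so the
package includes seeded generators that emulate both designs' statistical
structure (`gen_matched_cohort()`, `gen_two_sample_gwas()`); every
estimator is validated by planted-parameter recovery and by independent
oracles (grid search, generic WLS, `survival::clogit`, `metafor`).

## Worked example

```r
library(bilimr)

# serological arm: 658 matched male pairs, planted OR 1.19 per 1-SD log-UCB
cc  <- cohort_config(n_pairs = 658, sex = "male",
                     causal_logor_per_sd = log(1.19), seed = 42)
coh <- standardize_log_exposure(gen_matched_cohort(cc))
clogit_fit(coh, covariates = c("bmi", "alcohol"))
#> conditional logistic (1:1): OR per 1-SD 1.263 (95% CI 1.128-1.414),
#>   p 5.36e-05; 658 informative pairs

# MR arm: 115-variant instrument, planted causal OR 1.07
gw  <- gen_two_sample_gwas(gwas_config(causal_logor_per_sd = log(1.07), seed = 7))
set <- harmonize(gw$exposure, gw$outcome)
set
#> instrument_set: 115 variants, R2 = 0.1987, F = 684.7 (n = 317639)
wald_ratio(set$instruments[1, ])          # lead variant alone
#> wald_ratio: OR 1.093 (95% CI 1.047-1.141), beta 0.0887 (SE 0.0219), ...
rest <- leave_out(set, set$instruments$snp_id[1])
ivw_mre(rest)
#> ivw_mre: OR 1.161 (95% CI 1.050-1.284), beta 0.1495 (SE 0.0513), ...

# between-sex heterogeneity from printed ORs and CIs
sex_heterogeneity(list(beta = log(1.07), se = se_from_ci(1.07, 1.02, 1.12)),
                  list(beta = log(1.01), se = se_from_ci(1.01, 0.96, 1.06)))
#> Q = 2.756 (df 1), I2 = 63.7%, p = 0.0969
```

The single-replicate ORs above scatter around their planted values
(1.19, 1.07); averaged over hundreds of replicates they recover them to
the third decimal (see below). The I² line reconstructs the between-sex
contrast of the lead-variant MR estimates from their published intervals.

## The scripted workflow

`analysis/` holds numbered drivers that run the whole study shape on
synthetic inputs and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R   # cohorts + GWAS summary stats (CSV/TSV)
Rscript analysis/02_serology.R   # serological tables incl. sub-sites
Rscript analysis/03_mr.R         # MR estimator suite, PRESSO, scatter plots
Rscript analysis/04_report.R     # orchestrated run + versioned JSON report
```

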