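---
title: "Methods: serological and Mendelian-randomization analysis of circulating bilirubin and colorectal cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serological and Mendelian-randomization analysis of circulating bilirubin and colorectal cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Bilirubin, the end product of heme catabolism, is a potent endogenous
antioxidant, and mild unconjugated hyperbilirubinemia (Gilbert's syndrome,
tagged by reduced *UGT1A1* promoter activity) has been hypothesized to
protect against oxidative-stress-related disease, including colorectal
cancer. Testing that hypothesis observationally is hard: serum bilirubin
responds to liver function, fasting, and lifestyle, all of which also
relate to cancer risk; and pre-clinical disease can itself move the
biomarker (reverse causation).

`bilimr` implements the two complementary designs used to attack this
question, sex-stratified throughout because colorectal cancer risk and
bilirubin physiology both differ by sex:

1. **A serological arm** — a nested case-control study with 1:1
   incidence-density matching, analysed by conditional logistic
   regression of case status on standardized log unconjugated bilirubin
   (log-UCB), with spline dose-response, effect-modification and tumour
   sub-site analyses, and liver-function exclusion filters.
2. **A Mendelian-randomization (MR) arm** — two-sample MR using a
   115-variant genetic instrument for total bilirubin (one *UGT1A1* lead
   variant explaining 16.9% of variance, 114 others jointly explaining
   3.1%) against colorectal-cancer GWAS summary statistics, with a suite
   of pleiotropy-robust estimators.

Because the underlying individual-level and consortium data are
access-controlled, the package ships a synthetic-data module that
reproduces the *statistical structure* of both designs, so every
estimator is exercised and validated end-to-end by planted-parameter
recovery.

## The serological model

For 1:1 matched pairs, the conditional likelihood of the usual logistic
model reduces exactly to a no-intercept binomial likelihood on
within-pair covariate differences (case minus control):

$$\ell(\beta) = \sum_{i} \log \sigma\!\left(\beta^\top (x_{i1} - x_{i0})\right),$$

where $\sigma$ is the logistic function. `clogit_fit()` builds that
difference design and maximizes the likelihood by iteratively reweighted
least squares; matching factors are absorbed by the pairing, so they must
not be entered as covariates. Categorical covariates are dummy-coded with
any missing value as its own `"missing"` level *before* differencing —
missingness is treated as a category, not dropped. Pairs whose difference
vector is all zero contribute a constant to the likelihood and are
counted as uninformative.

The exposure enters as the z-score of log exposure, so coefficients are
log-ORs per 1-SD of log-UCB. Standardization defaults to sex-specific
moments (`sd_scope = "sex_specific"`) because every model is
sex-stratified; pooled moments are available by flag. The choice was
genuinely open; sex-specific is the coherent reading when the two sexes
are analysed as separate studies.

Nonlinearity is assessed with a three-knot restricted cubic spline at the
10th/50th/90th percentiles (one nonlinear basis term, hand-coded in the
truncated-power form, zero at and below the first knot) plus a Wald test
on the nonlinear coefficient. The plotted dose-response curve is anchored
at the first (10th-percentile) knot — the reference point was unstated in
the design and had to be fixed somewhere reproducible.

Effect modification fits stratum-specific exposure coefficients inside
the multivariable model and Wald-tests their equality, which is the same
test as on multiplicative interaction terms but yields the per-stratum
ORs directly. Continuous modifiers are dichotomized at the median by
default (with the continuous option open to the user); modifiers must be
pair-concordant — for member-varying modifiers such as genotype, only
concordant pairs are analysed and the discordant count is reported, which
mirrors how genotype-stratified matched analyses are usually presented
and explains stratum totals summing to fewer pairs than the cohort.

Sub-site heterogeneity uses a competing-risks stratified conditional
likelihood: each case is compared with its matched control and the
exposure coefficient is indexed by the case's tumour sub-site.
Overlapping colon lesions count toward all-colon only and are excluded
from the proximal-vs-distal contrast. Heterogeneity defaults to a Wald
contrast (a likelihood-ratio variant is available).

The liver screen computes the BTR index (molar BCAA:tyrosine) and
Fischer's ratio (BCAA:(tyrosine + phenylalanine)) and removes whole pairs
in which either member falls below either threshold — subclinical liver
dysfunction both depresses these ratios and raises bilirubin, so such
subjects can induce spurious exposure-outcome association.

## The MR model

Each harmonized variant $j$ carries an exposure effect $\hat\beta_{Xj}$
(SD units of total bilirubin, with SE) and an outcome effect
$\hat\beta_{Yj}$ (log-OR of colorectal cancer, with SE), estimated in
non-overlapping samples. Under the instrumental-variable assumptions the
per-variant Wald ratio $\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$
estimates the causal log-OR per 1-SD of exposure.

Estimators provided (all operating on an `instrument_set`):

* `wald_ratio()` — single variant; first-order delta SE
  $s_{Yj}/|\hat\beta_{Xj}|$ by default (second-order by flag; the
  exposure effects here are precise enough that the two differ in the
  fourth decimal).
* `ivw_mre()` — weighted regression through the origin, weights
  $1/s_{Yj}^2$; the SE is inflated by $\sqrt{\max(1, Q/(k-1))}$, the
  multiplicative random-effects scale.
* `likelihood_based()` — maximum likelihood under
  $\hat\beta_{Xj} \sim N(\xi_j, s_{Xj}^2)$,
  $\hat\beta_{Yj} \sim N(\theta\,\xi_j, s_{Yj}^2)$ with zero
  cross-correlation (the outcome consortia exclude the exposure
  discovery sample). The nuisance means $\xi_j$ are profiled out in
  closed form; $\theta$ is found by one-dimensional optimization and its
  SE from the numerical curvature of the profile log-likelihood. The
  profile (rather than full-likelihood) construction was an open choice;
  it is exact for the point estimate and its curvature SE agrees with
  the IVW fixed-effect SE in the no-measurement-error limit.
* `egger()` — weighted regression *with* intercept after orienting all
  variants to the exposure-increasing allele; the intercept estimates
  directional pleiotropy and is tested against a t-distribution with
  $k-2$ df.
* `weighted_median()` — inverse-variance-weighted median of the Wald
  ratios, interpolated at cumulative weight 0.5 (percentile convention);
  consistent while valid instruments retain a majority of the weight.
  SE by seeded parametric bootstrap.
* `mode_based()` — the simple (unweighted) mode of a normal-kernel
  density over the Wald ratios, bandwidth `bandwidth_factor` (default 1)
  times the modified Silverman rule
  $0.9\min(\mathrm{sd},\mathrm{mad})\,k^{-1/5}$, located by fine-grid
  search (4096 points spanning the ratios ±3 bandwidths); consistent
  when the largest group of equal-ratio instruments is valid. SE by
  seeded parametric bootstrap.
* `run_presso()` — MR-PRESSO: observed inverse-variance-weighted
  residual sum of squares about leave-one-out IVW fits, with a
  simulated null (`n_sim` draws of both effect vectors from their SEs
  under the leave-one-out model). Global, per-variant outlier
  (Bonferroni) and distortion tests; empirical p-values use
  $(r+1)/(n+1)$ so they are never zero, and with no flagged outliers
  the distortion p is reported as `NA`, never fabricated.

Instrument diagnostics follow the standard forms: per-variant variance
explained $2p(1-p)\beta^2$ for a standardized trait, and
$F = \frac{n-k-1}{k}\cdot\frac{R^2}{1-R^2}$. Two arithmetic wrinkles in
the published diagnostics are worth recording: the 114-variant set
reproduces $F = 89.1$ exactly from $R^2 = 0.031$, but the headline
115-variant $F = 696.5$ is not recoverable from the rounded
$R^2 = 20.0\%$ (which gives $\approx 690.3$; the published figure
implies an unrounded $R^2 \approx 0.2014$). The package computes, never
hard-codes, both.

Harmonization aligns outcome effects to the exposure effect allele
(negating the log-OR and flipping the frequency when the tables are
recorded on opposite alleles), then orients every instrument to the
exposure-increasing allele, a pure relabeling that all estimators are
invariant to but which gives scatter plots a positive x-axis.
Strand-ambiguous (A/T, C/G) variants are dropped or replaced by a
supplied proxy in LD $R^2 > 0.8$; frequency-based palindromic rescue is
deliberately not attempted. Genotyping QC removes variants by call rate
(< 0.98 by default, the stricter of the two source consortia's
thresholds), Hardy-Weinberg p < 1e-4 in controls, or MAF ≤ 1%.

Between-sex heterogeneity uses fixed-effect Cochran's Q with 1 df and
$I^2 = \max(0, (Q-\mathrm{df})/Q) \times 100$, with SEs reconstructible
from printed CIs via `se_from_ci()`. Recomputing the published
lead-variant comparison from its printed CIs gives $I^2 = 63.7\%$,
$p = 0.097$ (printed: 64.0%, 0.10); the analogous recomputation for the
114-variant estimates gives $I^2 \approx 53\%$ rather than the printed
39.0% — the printed CIs are rounded to two decimals, and the statistic is
sensitive to that rounding, so this quantity is documented rather than
targeted.

`mr_power_binary()` implements the conventional normal approximation
$\Phi\!\big(\sqrt{N R^2 \phi(1-\phi)}\,|\log\mathrm{OR}| - z_{1-\alpha/2}\big)$;
at the study's sex-stratified sample sizes and $R^2 = 0.20$ it returns
0.87 for OR 1.065. The formula is documented as what it is and makes no
claim to reproduce any externally computed power figure.

## What the synthetic generators emulate

`gen_matched_cohort()` draws, per pair, two members with log-normal
exposure whose standardized log value is
$z = \beta_g (g - 2p) + \varepsilon$, with genotype $g$ Hardy-Weinberg at
the lead-allele frequency and $\beta_g$ sized so the variant explains a
set fraction of variance (16.9% by default; total variance fixed at 1).
Case status is assigned *within* the pair with the exact conditional
probability $e^{\eta_1}/(e^{\eta_1}+e^{\eta_2})$ over the planted linear
predictor, so the planted log-OR is exactly the conditional-logistic
estimand and recovery tests are unbiased by construction rather than by
asymptotics. Defaults encode the study conditions: 658 male / 728 female
pairs; exposure moments matched per sex to the published baseline table
(men 4.3 ± 2.6, women 3.2 ± 1.8 µmol/L, mapped to log-normal
parameters); lead-allele frequency 0.39 (read off the published genotype
distribution); ~2% categorical missingness; tumour sub-sites drawn with
the published case mix (374:412:80:520); a clinically normal amino-acid
panel for the liver indices. Where the design gave no value (covariate
means/SDs beyond the baseline table, the modest default covariate
effects on risk), values a nutritional-epidemiology cohort would call
unremarkable were fixed once and are stated in `cohort_config()`.

`gen_two_sample_gwas()` draws independent variants with MAF uniform on
[0.05, 0.5] and rescales the true exposure effects so the realized
variance explained equals the lead/other split *exactly* (0.169 + 0.031
by default). Observed effects add independent noise with the standard
first-order SEs for a standardized trait and for a log-OR
($1/\sqrt{2pq\,n}$ and $1/\sqrt{2pq\,n_1 n_0/n}$); outcome effects are
$\theta \times$ true exposure effect plus optional directional
pleiotropy and planted outlier offsets. What it does *not* simulate: LD
between instruments (the real instrument was pruned to $R^2 < 0.001$, so
independence is the design assumption), imputation quality, population
stratification, or sample overlap. Passing recovery tests therefore
demonstrates estimator correctness under the stated model, not
robustness to those real-data pathologies.

## Numerical and reproducibility choices

* $z_{0.975}$ is fixed at 1.959964 everywhere, for bit-reproducible CIs.
* Every stochastic operation (generators, bootstraps, MR-PRESSO, the
  orchestrated run) takes an explicit seed; nothing consumes global RNG
  state implicitly, and per-stage seeds in `run_full_analysis()` are
  derived deterministically from the master seed within the 32-bit
  range. Fixed seed ⇒ byte-identical outputs, asserted in the tests.
* The conditional-logistic fit declares non-convergence (likely complete
  separation) when any coefficient exceeds 15 in absolute value; ties in
  the weighted median are handled by the interpolation itself (exact
  ties share cumulative weight).
* Degenerate inputs error early with the offending field or record
  named: nonpositive exposures, constant exposure in scope, zero
  amino-acid denominators, constant genotype, 1:1 violations, $b_X = 0$
  Wald ratios, boundary likelihood optima.

## Problem sizes used in validation

The test-suite simulations use the smallest designs that make each
property sharp: recovery at the study's own sizes (500 cohorts of
658/728 pairs; 200 two-sample draws at the published GWAS sample sizes),
error-rate calibration at 1000 replicates (Egger intercept, spline
nonlinearity), MR-PRESSO calibration at 500 null replicates of 10-variant
sets with 150 simulations each, and oracle equivalences on ≤ 12-variant
or ≤ 10-pair instances where brute-force enumeration is feasible.

## Known limitations

* The simple mode-based estimator is imprecise when per-variant ratios
  are noisy (its bootstrap SE on the 114-variant weak instrument is very
  large); that is a property of the estimator, reported honestly, not a
  defect of the implementation.
* The weighted median's robustness demonstration requires the *weight*
  share of invalid instruments below one half — with randomly sized
  effects, 40% of variants by count can exceed 50% of weight, which is
  outside the estimator's guarantee and is exercised as such in the
  tests.
* No multivariable MR, correlated-instrument IVW, or Bayesian
  model-averaging estimators; no multiple imputation of covariates; no
  Cox modelling — none were part of the analysis design.
* `interaction_test()` analyses pair-concordant modifier strata only;
  discordant pairs are set aside and counted rather than contributing
  partial information.
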