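test_that("wald_ratio computes by/bx with delta-method SE", {
  z <- list(bx = 0.2, sx = 0.01, by = 0, sy = 0.01)
  est0 <- wald_ratio(z)
  expect_equal(est0$beta, 0)
  expect_equal(est0$or_, 1)

  est <- wald_ratio(list(bx = 0.35, sx = 0.01, by = 0.0237, sy = 0.008))
  expect_equal(est$beta, 0.0237 / 0.35, tolerance = 1e-12)
  expect_equal(est$se, 0.008 / 0.35, tolerance = 1e-12)
  expect_equal(est$or_, exp(est$beta))

  # orientation invariance
  est2 <- wald_ratio(list(bx = -0.35, sx = 0.01, by = -0.0237, sy = 0.008))
  expect_equal(est2$beta, est$beta)
  expect_equal(est2$se, est$se)

  expect_error(wald_ratio(list(bx = 0, sx = 1, by = 1, sy = 1)),
               "undefined ratio")
  # second-order SE exceeds first-order
  s2 <- wald_ratio(list(bx = 0.35, sx = 0.05, by = 0.0237, sy = 0.008),
                   second_order = TRUE)
  expect_gt(s2$se, est$se)
})

test_that("ivw_mre equals the closed-form origin regression with Q-based scale", {
  # homogeneous instruments: Q = 0, scale 1
  hom <- make_set(bx = c(0.2, 0.4), by = c(0.02, 0.04), sy = c(0.01, 0.01))
  e <- ivw_mre(hom)
  expect_equal(e$beta, 0.1, tolerance = 1e-12)
  expect_equal(e$extras$Q, 0, tolerance = 1e-12)
  expect_equal(e$extras$scale, 1)

  # value derived from the stated closed form sum(bx*by)/sum(bx^2), equal sy
  s3 <- make_set(bx = c(0.2, 0.4, 0.1), by = c(0.02, 0.05, 0.005),
                 sy = rep(0.01, 3))
  expect_equal(ivw_mre(s3)$beta, 0.0245 / 0.21, tolerance = 1e-12)

  expect_error(ivw_mre(make_set(0.1, 0.01, 0.01)), "k >= 2")
})

test_that("ivw and egger match a generic weighted-least-squares oracle", {
  set.seed(41)
  for (i in 1:5) {
    k <- sample(4:10, 1)
    s <- make_set(bx = runif(k, 0.05, 0.5), by = rnorm(k, 0.02, 0.05),
                  sy = runif(k, 0.005, 0.05), sx = runif(k, 0.001, 0.01))
    d <- s$instruments
    o_ivw <- lm(by ~ bx - 1, data = d, weights = 1 / d$sy^2)
    expect_equal(ivw_mre(s)$beta, unname(coef(o_ivw)), tolerance = 1e-10)
    o_egg <- lm(by ~ bx, data = d, weights = 1 / d$sy^2)
    e <- egger(s)
    expect_equal(e$beta, unname(coef(o_egg)[2]), tolerance = 1e-10)
    expect_equal(e$extras$intercept, unname(coef(o_egg)[1]), tolerance = 1e-10)
  }
})

test_that("egger recovers an exact linear pleiotropy structure", {
  bxv <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  s <- make_set(bx = bxv, by = 0.02 + 0.1 * bxv, sy = rep(0.01, 5))
  e <- egger(s)
  expect_equal(e$beta, 0.1, tolerance = 1e-10)
  expect_equal(e$extras$intercept, 0.02, tolerance = 1e-10)
  expect_equal(e$extras$rss, 0, tolerance = 1e-10)
  expect_error(egger(make_set(c(0.1, 0.2), 0.01, c(0.01, 0.01))), "k >= 3")
})

test_that("likelihood-based MR attains its analytic limits", {
  # no-measurement-error limit: equals fixed-effect IVW
  s <- make_set(bx = c(0.2, 0.3, 0.4), by = c(0.025, 0.027, 0.045),
                sy = c(0.01, 0.02, 0.015), sx = rep(1e-8, 3))
  ivw_fe <- with(s$instruments, sum(bx * by / sy^2) / sum(bx^2 / sy^2))
  expect_equal(likelihood_based(s)$beta, ivw_fe, tolerance = 1e-6)

  # single strong instrument: equals the Wald ratio
  s1 <- make_set(bx = 0.5, by = 0.04, sy = 0.01, sx = 0.001)
  expect_equal(likelihood_based(s1)$beta,
               wald_ratio(s1$instruments[1, ])$beta, tolerance = 1e-6)
})

test_that("weighted median interpolates at cumulative weight 0.5", {
  # all ratios equal
  s <- make_set(bx = c(0.2, 0.3, 0.4), by = c(0.02, 0.03, 0.04),
                sy = c(0.01, 0.012, 0.015))
  expect_equal(weighted_median(s, n_boot = 50, seed = 1)$beta, 0.1,
               tolerance = 1e-10)
  # equal weights, middle order statistic
  s2 <- make_set(bx = c(1, 1, 1), by = c(0, 0.1, 0.5), sy = rep(0.01, 3))
  expect_equal(weighted_median(s2, n_boot = 50, seed = 1)$beta, 0.1,
               tolerance = 1e-10)
  expect_error(weighted_median(make_set(c(1, 1), c(0, 1), c(1, 1))), "k >= 3")
})

test_that("weighted median matches an exhaustive cumulative-weight scan", {
  set.seed(43)
  for (i in 1:5) {
    k <- sample(4:12, 1)
    s <- make_set(bx = runif(k, 0.1, 0.6), by = rnorm(k, 0.03, 0.04),
                  sy = runif(k, 0.005, 0.05))
    d <- s$instruments
    r <- d$by / d$bx
    w <- (d$bx / d$sy)^2
    o <- order(r); r <- r[o]; w <- w[o] / sum(w)
    p <- cumsum(w) - w / 2
    j <- max(which(p < 0.5))
    oracle <- r[j] + (r[j + 1] - r[j]) * (0.5 - p[j]) / (p[j + 1] - p[j])
    expect_equal(weighted_median(s, n_boot = 50, seed = 1)$beta, oracle,
                 tolerance = 1e-10)
  }
})

test_that("mode-based estimate finds the dominant ratio cluster", {
  # all ratios equal -> that value, any bandwidth
  s <- make_set(bx = rep(0.3, 4), by = rep(0.03, 4), sy = rep(0.01, 4))
  for (bwf in c(0.5, 1, 2)) {
    expect_equal(mode_based(s, bandwidth_factor = bwf, n_boot = 50,
                            seed = 1)$beta, 0.1, tolerance = 1e-4)
  }
  # 9 clustered ratios plus one far outlier
  ratios <- c(0.1 + seq(-0.001, 0.001, length.out = 9), 1.0)
  s2 <- make_set(bx = rep(1, 10), by = ratios, sy = rep(0.01, 10))
  est <- mode_based(s2, n_boot = 50, seed = 1)
  expect_equal(est$beta, 0.1, tolerance = 0.01)
  # matches a fine-grid density argmax oracle at the same bandwidth
  h <- est$extras$bandwidth
  grid <- seq(-0.2, 1.2, length.out = 200001)
  dens <- vapply(grid, function(t) sum(dnorm((t - ratios) / h)), numeric(1))
  expect_equal(est$beta, grid[which.max(dens)], tolerance = 1e-3)
})

test_that("estimators are invariant to per-variant sign flips and ordering", {
  set.seed(47)
  k <- 12
  s <- make_set(bx = runif(k, 0.1, 0.5), by = rnorm(k, 0.04, 0.03),
                sy = runif(k, 0.01, 0.03), sx = runif(k, 0.002, 0.01))
  d <- s$instruments
  flip <- sample(c(-1, 1), k, replace = TRUE)
  d2 <- d; d2$bx <- d$bx * flip; d2$by <- d$by * flip
  perm <- sample(k)
  d2 <- d2[perm, ]
  s2 <- new_instrument_set(d2, s$exposure_n)
  for (f in list(ivw_mre, egger, likelihood_based)) {
    expect_equal(f(s2)$beta, f(s)$beta, tolerance = 1e-8)
  }
  expect_equal(weighted_median(s2, n_boot = 50, seed = 9)$beta,
               weighted_median(s, n_boot = 50, seed = 9)$beta,
               tolerance = 1e-10)
  expect_equal(mode_based(s2, n_boot = 50, seed = 9)$beta,
               mode_based(s, n_boot = 50, seed = 9)$beta, tolerance = 1e-6)
})

test_that("on homogeneous noiseless instruments every estimator returns the common ratio", {
  k <- 6
  bxv <- seq(0.1, 0.6, length.out = k)
  s <- make_set(bx = bxv, by = 0.25 * bxv, sy = rep(0.01, k),
                sx = rep(1e-9, k))
  expect_equal(ivw_mre(s)$beta, 0.25, tolerance = 1e-10)
  expect_equal(egger(s)$beta, 0.25, tolerance = 1e-8)
  expect_equal(likelihood_based(s)$beta, 0.25, tolerance = 1e-6)
  expect_equal(weighted_median(s, n_boot = 50, seed = 1)$beta, 0.25,
               tolerance = 1e-10)
  expect_equal(mode_based(s, n_boot = 50, seed = 1)$beta, 0.25,
               tolerance = 1e-4)
})

test_that("IVW is unbiased and its CI covers the planted effect without pleiotropy", {
  theta <- log(0.9)
  est <- matrix(NA_real_, 200, 3)
  for (i in 1:200) {
    gw <- gen_two_sample_gwas(gwas_config(n_snps = 40, lead_r2 = 0.05,
                                          other_r2_total = 0.05,
                                          causal_logor_per_sd = theta,
                                          seed = 5000 + i))
    e <- ivw_mre(harmonize(gw$exposure, gw$outcome))
    est[i, ] <- c(e$beta, log(e$ci_low), log(e$ci_high))
  }
  mc_se <- sd(est[, 1]) / sqrt(nrow(est))
  expect_lt(abs(mean(est[, 1]) - theta), 2 * mc_se)
  cover <- mean(est[, 2] <= theta & theta <= est[, 3])
  expect_gt(cover, 0.95 - 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("weighted median stays near truth with 40% pleiotropic instruments while IVW shifts", {
  theta <- 0.1
  wm <- ivw <- numeric(60)
  for (i in 1:60) {
    # precise instruments (large outcome sample) so the median's finite-noise
    # bias is negligible next to the planted directional pleiotropy; the
    # offsets go on the 8 lowest-weight variants (40% by count) so that the
    # valid instruments keep a majority of the weight, which is the
    # estimator's consistency condition
    gw <- gen_two_sample_gwas(gwas_config(n_snps = 20, lead_r2 = 0.01,
                                          other_r2_total = 0.19,
                                          outcome_cases = 2e7,
                                          outcome_controls = 2e7,
                                          causal_logor_per_sd = theta,
                                          seed = 7000 + i))
    s <- harmonize(gw$exposure, gw$outcome)
    w <- (s$instruments$bx / s$instruments$sy)^2
    out_idx <- order(w)[1:8]
    s$instruments$by[out_idx] <- s$instruments$by[out_idx] + 0.1
    wm[i] <- weighted_median(s, n_boot = 10, seed = i)$beta
    ivw[i] <- ivw_mre(s)$beta
  }
  expect_lt(abs(mean(wm) - theta), 3 * sd(wm) / sqrt(60) + 0.01)
  expect_gt(mean(ivw) - theta, 0.01)  # IVW visibly biased upward
})
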