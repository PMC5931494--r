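test_that("printed confidence intervals invert to log-OR standard errors", {
  # 17% (13%-21%) lower risk: OR 0.83 (0.79-0.87)
  expect_equal(ci_to_se(0.83, 0.79, 0.87), 0.024607, tolerance = 1e-4)
  # round trip se -> CI -> se
  se <- 0.0731
  ci <- exp(log(0.9) + c(-1, 1) * 1.959964 * se)
  expect_equal(ci_to_se(0.9, ci[1], ci[2]), se, tolerance = 1e-12)
  expect_warning(degenerate <- ci_to_se(1, 1, 1), "degenerate")
  expect_equal(degenerate, 0)
  expect_error(ci_to_se(0.9, -0.1, 1), "positive")
  expect_error(ci_to_se(0.9, 0.95, 1), "ci_low")
})

test_that("per-allele effects rescale to per-25-nmol/l correctly", {
  # per-allele OR 0.97 through a 2.87 nmol/l score effect
  e <- scale_per_25(log(0.97), 0.02, 2.87)
  expect_equal(e$or, exp(25 * log(0.97) / 2.87), tolerance = 1e-12)
  expect_equal(e$or, 0.767, tolerance = 1e-3)
  # unit case: beta_exposure = 25 leaves the estimate unchanged
  e2 <- scale_per_25(-0.2, 0.05, 25)
  expect_equal(e2$beta, -0.2)
  expect_equal(e2$se, 0.05)
  # null invariance
  expect_equal(scale_per_25(0, 0.01, 3.1)$or, 1)
  expect_error(scale_per_25(0.1, 0.01, -2), "orientation")
})

test_that("Wald ratios reproduce hand-computed printed combinations", {
  # CYP2R1: per-allele OR 1.00 -> exactly null whatever the denominator
  expect_equal(wald_ratio(0.95, 0.42, log(1.00), 0.02)$beta, 0)
  # GC/DBP: per-allele OR 1.01 with 3.59 nmol/l per allele
  expect_equal(wald_ratio(3.59, 0.44, log(1.01), 0.0229)$or, 1.0718,
               tolerance = 1e-3)
  expect_equal(wald_ratio(2.84, 0.41, 0, 0.05)$beta, 0)
  expect_error(wald_ratio(0.05, 0.3, 0.1, 0.05), "weak instrument")
  # second-order SE is never smaller than first-order
  a <- wald_ratio(2.84, 0.41, -0.03, 0.021)
  b <- wald_ratio(2.84, 0.41, -0.03, 0.021, second_order = TRUE)
  expect_gte(b$se, a$se)
})

test_that("fixed-effect IVW matches its closed form and the WLS oracle", {
  # two identical estimates: unchanged point, se / sqrt(2)
  e <- ivw(c(-0.1, -0.1), c(0.05, 0.05))
  expect_equal(e$beta, -0.1)
  expect_equal(e$se, 0.05 / sqrt(2))
  expect_equal(e$Q, 0)
  set.seed(41)
  for (i in 1:25) {
    k <- sample(2:12, 1)
    b <- rnorm(k, -0.1, 0.2)
    s <- runif(k, 0.02, 0.4)
    got <- ivw(b, s)
    oracle <- wls_oracle(b, s)
    expect_equal(got$beta, oracle$beta, tolerance = 1e-10)
    expect_equal(got$se, oracle$se, tolerance = 1e-10)
  }
  expect_error(ivw(-0.1, 0.05), "at least 2")
  expect_error(ivw(c(0, 0), c(0.1, -0.1)), "positive")
})

test_that("IVW agrees with an independent meta-analysis implementation", {
  skip_if_not_installed("metafor")
  set.seed(42)
  b <- rnorm(8, -0.15, 0.1)
  s <- runif(8, 0.03, 0.2)
  got <- ivw(b, s)
  ref <- metafor::rma(yi = b, sei = s, method = "FE")
  expect_equal(got$beta, as.numeric(ref$beta), tolerance = 1e-8)
  expect_equal(got$se, ref$se, tolerance = 1e-8)
  expect_equal(got$Q, ref$QE, tolerance = 1e-8)
})

test_that("MR-Egger recovers exact lines and reduces to OLS when unweighted", {
  # instruments exactly on a line through the origin: zero intercept
  bx <- c(1, 2, 3, 4)
  by <- -0.01 * bx
  out <- egger(bx, rep(0.1, 4), by, rep(0.02, 4))
  slope <- out[out$method == "egger_slope", ]
  inter <- out[out$method == "egger_intercept", ]
  expect_equal(inter$beta, 0, tolerance = 1e-12)
  expect_equal(slope$beta, -0.01 * 25, tolerance = 1e-12)
  # equal outcome SEs: coefficients equal ordinary least squares
  set.seed(43)
  bx2 <- runif(6, 0.5, 4)
  by2 <- -0.008 * bx2 + 0.003 + rnorm(6, 0, 0.01)
  out2 <- egger(bx2, rep(0.1, 6), by2, rep(0.05, 6))
  ols <- lm(by2 ~ bx2)
  expect_equal(out2$beta[out2$method == "egger_slope"] / 25,
               unname(coef(ols)["bx2"]), tolerance = 1e-10)
  expect_equal(out2$beta[out2$method == "egger_intercept"],
               unname(coef(ols)["(Intercept)"]), tolerance = 1e-10)
  expect_error(egger(c(1, 2), c(0.1, 0.1), c(0, 0), c(0.1, 0.1)),
               "at least 3")
  expect_error(egger(c(-1, 2, 3), rep(0.1, 3), rep(0, 3), rep(0.1, 3)),
               "orientation")
})

test_that("weighted median matches brute-force enumeration and trivial cases", {
  # all ratios equal: estimate is that ratio
  wm <- weighted_median(c(1, 2, 4), rep(0.1, 3), c(-0.004, -0.008, -0.016),
                        rep(0.01, 3), n_boot = 100, seed = 1)
  expect_equal(wm$beta, -0.1, tolerance = 1e-10)
  # explicit 3-instrument case against the enumeration oracle
  bx <- c(2, 1.5, 3); sy <- c(0.02, 0.015, 0.01)
  by <- c(-0.01, 0.002, -0.02)
  r <- 25 * by / bx
  w <- bx^2 / (25^2 * sy^2)
  wm2 <- weighted_median(bx, rep(0.1, 3), by, sy, n_boot = 100, seed = 2)
  expect_equal(wm2$beta, wmedian_oracle(r, w), tolerance = 1e-12)
  # random sets up to 10 SNPs
  set.seed(44)
  for (i in 1:20) {
    k <- sample(2:10, 1)
    bx <- runif(k, 0.5, 4); sy <- runif(k, 0.005, 0.05)
    by <- rnorm(k, -0.006 * bx, sy)
    got <- weighted_median(bx, rep(0.1, k), by, sy, n_boot = 50, seed = i)
    expect_equal(got$beta,
                 wmedian_oracle(25 * by / bx, bx^2 / (25^2 * sy^2)),
                 tolerance = 1e-12)
  }
  # bootstrap SE is seeded: identical seeds identical SEs
  a <- weighted_median(bx, rep(0.1, length(bx)), by, sy, n_boot = 200, seed = 9)
  b <- weighted_median(bx, rep(0.1, length(bx)), by, sy, n_boot = 200, seed = 9)
  expect_identical(a$se, b$se)
})

test_that("weighted median stays consistent with under half the weight invalid", {
  # 10 valid + 4 invalid instruments; the invalid set carries < 50% of the
  # weight, so the weighted median stays near the truth while IVW is dragged
  # toward the pleiotropic cluster
  set.seed(45)
  true <- log(0.86)
  ests <- replicate(80, {
    bx <- runif(14, 2, 4)
    sy <- runif(14, 0.002, 0.004)
    by <- rnorm(14, true / 25 * bx, sy)
    by[11:14] <- by[11:14] + 0.08 # directional pleiotropy
    w <- bx^2 / sy^2
    if (sum(w[11:14]) / sum(w) >= 0.5) return(c(NA_real_, NA_real_))
    c(weighted_median(bx, rep(0.1, 14), by, sy, n_boot = 2, seed = 1)$beta,
      ivw(25 * by / bx, 25 * sy / bx)$beta)
  })
  wm <- ests[1, !is.na(ests[1, ])]
  iv <- ests[2, !is.na(ests[2, ])]
  expect_lt(abs(mean(wm) - true), 0.025)
  expect_gt(abs(mean(iv) - true), 3 * abs(mean(wm) - true))
})

test_that("per-25-nmol/l estimates are invariant to exposure-unit rescaling", {
  bx <- c(2.84, 0.95, 3.59); sy <- c(0.02, 0.021, 0.023)
  by <- c(-0.0034, -0.0011, -0.0043)
  base <- ivw(25 * by / bx, 25 * sy / bx)
  for (c_scale in c(0.1, 2, 40)) {
    # exposure measured in different units: both sides of the ratio rescale
    scaled <- ivw(25 * (by / c_scale) / (bx / c_scale),
                  25 * (sy / c_scale) / (bx / c_scale))
    expect_equal(scaled$beta, base$beta, tolerance = 1e-12)
    expect_equal(scaled$se, base$se, tolerance = 1e-12)
  }
})

test_that("score IV on a single-SNP score equals that SNP's Wald ratio", {
  panel <- ckb_snp_panel()[1, ]
  cfg <- generator_config(n_individuals = 20000, snps = panel,
                          measured_subset_fraction = 0.5,
                          causal_or_per25 = 0.8)
  co <- simulate_cohort(cfg, seed = 46)
  sm <- cv_weights(co, k = 5, seed = 3)
  iv <- score_iv(co, sm)
  # a one-SNP score is the dosage itself (weights cancel in the normalised
  # score), so the per-allele outcome effect equals the SNP's own effect
  out_eff <- per_snp_outcome_effects(co, snp_ids = "rs12785878")
  wr <- wald_ratio(sm$per_allele_effect, sm$se,
                   out_eff$beta_outcome, out_eff$se_outcome)
  expect_equal(iv$beta, wr$beta, tolerance = 1e-8)
  expect_equal(iv$se, wr$se, tolerance = 1e-8)
})

test_that("mr_all_methods agree under no pleiotropy with equal precision", {
  set.seed(47)
  true <- log(0.86)
  gap <- replicate(40, {
    bx <- runif(6, 1.5, 3.5)
    sy <- rep(0.012, 6)
    by <- rnorm(6, true / 25 * bx, sy)
    instr <- data.frame(snp_id = paste0("s", 1:6),
                        beta_exposure = bx, se_exposure = rep(0.1, 6),
                        beta_outcome = by, se_outcome = sy)
    res <- mr_all_methods(instr, n_boot = 2, seed = 1)
    c(res$beta[res$method == "ivw"],
      res$beta[res$method == "egger_slope"],
      res$beta[res$method == "weighted_median"])
  })
  m <- rowMeans(gap)
  mcse <- apply(gap, 1, sd) / sqrt(ncol(gap))
  expect_lt(abs(m[1] - true), 3 * mcse[1])
  expect_lt(abs(m[2] - true), 3 * mcse[2])
  expect_lt(abs(m[3] - true), 3 * mcse[3])
})
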