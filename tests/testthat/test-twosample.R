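test_that("harmonization orients every record to the exposure-increasing allele", {
  rec <- data.frame(snp = c("rs1", "rs2"), effect_allele = c("A", "C"),
                    other_allele = c("G", "T"),
                    beta_exp = c(-0.1, 0.2), se_exp = 0.01,
                    beta_out = c(0.5, -0.3), se_out = 0.1)
  h <- suppressMessages(harmonize(rec))
  expect_equal(h$beta_exp, c(0.1, 0.2))
  expect_equal(h$beta_out, c(-0.5, -0.3))
  expect_equal(h$effect_allele, c("G", "C"))
  expect_equal(h$other_allele, c("A", "T"))
  expect_equal(h$flipped, c(TRUE, FALSE))
  expect_equal(h$se_out, c(0.1, 0.1))
})

test_that("zero-exposure records are excluded and palindromes flagged", {
  rec <- data.frame(snp = c("rs1", "rs2", "rs3"),
                    effect_allele = c("A", "C", "A"),
                    other_allele = c("T", "G", "C"),
                    beta_exp = c(0.1, 0, 0.2), se_exp = 0.01,
                    beta_out = c(0.5, 0.1, -0.3), se_out = 0.1)
  expect_message(h <- harmonize(rec), "zero exposure beta")
  expect_equal(nrow(h), 2L)
  expect_equal(h$palindromic, c(TRUE, FALSE))
})

test_that("IVW estimates are invariant to input allele orientation", {
  pan <- quick_panel(5, causal_beta = 0.4, flip_fraction = 0)
  base <- ivw_multi(suppressMessages(harmonize(pan)))
  for (r in 1:100) {
    flip <- with(list(k = nrow(pan)), sample(c(TRUE, FALSE), nrow(pan),
                                             replace = TRUE))
    p2 <- pan
    p2$beta_exp[flip] <- -p2$beta_exp[flip]
    p2$beta_out[flip] <- -p2$beta_out[flip]
    tmp <- p2$effect_allele[flip]
    p2$effect_allele[flip] <- p2$other_allele[flip]
    p2$other_allele[flip] <- tmp
    h2 <- suppressMessages(harmonize(p2))
    h2 <- h2[order(h2$snp), ]
    est <- ivw_multi(h2)
    expect_equal(est$beta, base$beta, tolerance = 1e-12)
    expect_equal(est$se, base$se, tolerance = 1e-12)
    one <- ivw_single(h2[1, ])
    flip1 <- h2$snp[1]
    raw1 <- p2[p2$snp == flip1, ]
    expect_equal(one$beta, raw1$beta_out / raw1$beta_exp, tolerance = 1e-12)
  }
})

test_that("Egger is orientation-sensitive pre-harmonization, invariant after", {
  pan <- quick_panel(6, causal_beta = 0.4, pleiotropy_mean = 0.05,
                     pleiotropy_sd = 0.03, flip_fraction = 0)
  h <- suppressMessages(harmonize(pan))
  e_base <- egger_regression(h, n_boot = 50, seed = 1)

  p2 <- pan
  flip <- c(TRUE, FALSE)[1 + (seq_len(nrow(pan)) %% 2)]
  p2$beta_exp[flip] <- -p2$beta_exp[flip]
  p2$beta_out[flip] <- -p2$beta_out[flip]
  tmp <- p2$effect_allele[flip]
  p2$effect_allele[flip] <- p2$other_allele[flip]
  p2$other_allele[flip] <- tmp

  # refusing to fit a mis-oriented panel is part of the contract
  expect_error(egger_regression(p2, n_boot = 50, seed = 1), "harmonize")
  # force the mis-oriented fit: the point estimates change
  p2_forced <- p2
  attr(p2_forced, "harmonized") <- TRUE
  e_raw <- egger_regression(p2_forced, n_boot = 50, seed = 1)
  expect_gt(abs(e_raw$intercept - e_base$intercept) +
              abs(e_raw$slope - e_base$slope), 1e-6)

  # after harmonization the flips are undone exactly
  h2 <- suppressMessages(harmonize(p2))
  h2 <- h2[match(h$snp, h2$snp), ]
  e2 <- egger_regression(h2, n_boot = 50, seed = 1)
  expect_equal(e2$intercept, e_base$intercept, tolerance = 1e-12)
  expect_equal(e2$slope, e_base$slope, tolerance = 1e-12)
})

test_that("fixed-effects meta-analysis matches hand-computed values", {
  m <- fixed_effects_meta(c(1, 1, 1), c(1, 1, 1))
  expect_equal(m$pooled_beta, 1)
  expect_equal(m$q_statistic, 0)
  expect_equal(m$i2, 0)

  # w = (1,1): pooled = 1, se = 1/sqrt(2), Q = 1*(0-1)^2 + 1*(2-1)^2 = 2,
  # I2 = (2-1)/2 = 50%
  m2 <- fixed_effects_meta(c(0, 2), c(1, 1))
  expect_equal(m2$pooled_beta, 1)
  expect_equal(m2$pooled_se, 1 / sqrt(2))
  expect_equal(m2$q_statistic, 2)
  expect_equal(m2$i2, 50)
  expect_equal(m2$p_heterogeneity, pchisq(2, 1, lower.tail = FALSE))

  expect_message(m1 <- fixed_effects_meta(0.3, 0.1), "single study")
  expect_equal(m1$pooled_beta, 0.3)
  expect_equal(m1$pooled_se, 0.1)
  expect_equal(m1$i2, 0)

  expect_error(fixed_effects_meta(numeric(0), numeric(0)), "no effects")
})

test_that("I2 is floored at zero when Q does not exceed its df", {
  for (s in 1:20) {
    pan <- harmonized_panel(s, causal_beta = 0.5, se_outcome = 5)
    ratios <- pan$beta_out / pan$beta_exp
    ses <- pan$se_out / abs(pan$beta_exp)
    m <- fixed_effects_meta(ratios, ses)
    if (m$q_statistic <= m$df) expect_identical(m$i2, 0)
    expect_gte(m$i2, 0)
    expect_lte(m$i2, 100)
  }
})

test_that("single-SNP IVW follows the ratio formula", {
  e1 <- ivw_single(list(beta_exp = 1, beta_out = 2, se_out = 1))
  expect_equal(e1$beta, 2)
  expect_equal(e1$se, 1)

  e2 <- ivw_single(list(beta_exp = 0.5, beta_out = 1, se_out = 2))
  expect_equal(e2$beta, 2)
  expect_equal(e2$se, 4)

  # delta-method oracle ignoring the exposure SE reduces to se_out/|X|
  e3 <- ivw_single(list(beta_exp = 0.2, beta_out = -0.1, se_out = 0.3))
  expect_equal(e3$beta, -0.5)
  expect_equal(e3$se, 1.5)
  delta_oracle <- sqrt(0.3^2 / 0.2^2 + (-0.1)^2 * 0^2 / 0.2^4)
  expect_equal(e3$se, delta_oracle)
  # with the exposure SE switched on, the SE can only grow
  e3d <- ivw_single(list(beta_exp = 0.2, beta_out = -0.1, se_out = 0.3,
                         se_exp = 0.05), delta_se = TRUE)
  expect_gt(e3d$se, e3$se)

  expect_error(ivw_single(list(beta_exp = 0, beta_out = 1, se_out = 1)),
               "undefined")
})

test_that("multi-SNP IVW equals the weighted-through-origin oracle", {
  pan <- data.frame(snp = c("a", "b"), effect_allele = "A", other_allele = "G",
                    beta_exp = c(1, 1), se_exp = 0.01,
                    beta_out = c(1, 3), se_out = c(1, 1))
  est <- ivw_multi(pan)
  expect_equal(est$beta, 2)
  expect_equal(est$se, 1 / sqrt(2))

  # independent oracle: weighted least squares through the origin via lm
  pan2 <- harmonized_panel(12, causal_beta = 0.3)
  est2 <- ivw_multi(pan2)
  or <- lm(beta_out ~ beta_exp - 1, data = pan2, weights = 1 / pan2$se_out^2)
  expect_equal(est2$beta, unname(coef(or)), tolerance = 1e-10)

  # k copies of one SNP: same beta as the single-SNP ratio, se / sqrt(k)
  rec <- pan2[3, ]
  k <- 5
  stacked <- rec[rep(1, k), ]
  est_k <- ivw_multi(stacked)
  one <- ivw_single(rec)
  expect_equal(est_k$beta, one$beta, tolerance = 1e-12)
  expect_equal(est_k$se, one$se / sqrt(k), tolerance = 1e-12)

  expect_error(ivw_multi(pan2[1, ]), "ivw_single")
})

test_that("IVW equals the meta-analysis of per-SNP Wald ratios", {
  for (s in 1:25) {
    pan <- harmonized_panel(s, causal_beta = runif(1, -1, 1))
    ivw <- ivw_multi(pan)
    m <- fixed_effects_meta(pan$beta_out / pan$beta_exp,
                            pan$se_out / abs(pan$beta_exp))
    expect_equal(ivw$beta, m$pooled_beta, tolerance = 1e-10)
    expect_equal(ivw$se, m$pooled_se, tolerance = 1e-10)
  }
})

test_that("causal estimates scale inversely with the exposure units", {
  pan <- harmonized_panel(14, causal_beta = 0.5, pleiotropy_mean = 0.05,
                          pleiotropy_sd = 0.02)
  c_fac <- 2.5
  pan2 <- pan
  pan2$beta_exp <- pan$beta_exp * c_fac
  pan2$se_exp <- pan$se_exp * c_fac
  expect_equal(ivw_multi(pan2)$beta, ivw_multi(pan)$beta / c_fac,
               tolerance = 1e-12)
  expect_equal(ivw_single(pan2[1, ])$beta, ivw_single(pan[1, ])$beta / c_fac,
               tolerance = 1e-12)
  e1 <- egger_regression(pan, n_boot = 10, seed = 1)
  e2 <- egger_regression(pan2, n_boot = 10, seed = 1)
  expect_equal(e2$slope, e1$slope / c_fac, tolerance = 1e-12)
  expect_equal(e2$intercept, e1$intercept, tolerance = 1e-12)
})

test_that("Egger reproduces exact linear data and guards its preconditions", {
  x <- c(0.05, 0.1, 0.15, 0.2)
  pan <- data.frame(snp = paste0("rs", 1:4), effect_allele = "A",
                    other_allele = "G", beta_exp = x, se_exp = 0.01,
                    beta_out = 0.5 + 2 * x, se_out = 0.1)
  e <- egger_regression(pan, n_boot = 200, seed = 3)
  expect_equal(e$intercept, 0.5, tolerance = 1e-12)
  expect_equal(e$slope, 2, tolerance = 1e-12)
  # exact fit: zero dispersion, zero-width bootstrap intervals
  expect_equal(unname(diff(e$slope_ci)), 0, tolerance = 1e-10)

  expect_error(egger_regression(pan[1:2, ], n_boot = 10, seed = 1),
               "at least 3")
  pan_deg <- pan
  pan_deg$beta_exp <- 0.1
  expect_error(egger_regression(pan_deg, n_boot = 10, seed = 1),
               "unidentified")
})

test_that("Egger bootstrap is seed-deterministic and stable across seeds", {
  pan <- harmonized_panel(20, causal_beta = 0.5, pleiotropy_mean = 0.1,
                          pleiotropy_sd = 0.05)
  e1 <- egger_regression(pan, n_boot = 10000, seed = 101)
  e1b <- egger_regression(pan, n_boot = 10000, seed = 101)
  expect_identical(e1$slope_ci, e1b$slope_ci)
  expect_identical(e1$intercept_ci, e1b$intercept_ci)

  # quantile MC theory: each 2.5% endpoint has sd about 0.027*se at
  # B = 10^4, so seed-to-seed differences stay within ~0.1*se
  e2 <- egger_regression(pan, n_boot = 10000, seed = 202)
  expect_lt(max(abs(e1$slope_ci - e2$slope_ci)), 0.1 * e1$slope_se)
  expect_lt(max(abs(e1$intercept_ci - e2$intercept_ci)),
            0.1 * e1$intercept_se)

  # parametric scheme: same point fit, CIs in the same neighbourhood
  ep <- egger_regression(pan, n_boot = 10000, seed = 101,
                         scheme = "parametric")
  expect_identical(ep$slope, e1$slope)
  expect_lt(abs(ep$slope_ci[1] - e1$slope_ci[1]), 6 * e1$slope_se)
})
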