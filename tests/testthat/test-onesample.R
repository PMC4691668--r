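test_that("standardization log-transforms and z-scores with the sample SD", {
  # log of (1, e, e^2) is (0, 1, 2); sample SD (n-1 denominator) is 1
  expect_equal(standardize_log_exposure(c(1, exp(1), exp(2))), c(-1, 0, 1),
               tolerance = 1e-12)
  x <- exp(rnorm(200, 2, 0.3))
  z <- standardize_log_exposure(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)

  expect_error(standardize_log_exposure(rep(2, 5)), "constant")
  expect_error(standardize_log_exposure(c(1, 2, -3, 4)), "record.*3")

  grp <- rep(c("m", "f"), each = 100)
  zg <- standardize_log_exposure(x, group = grp)
  for (g in c("m", "f")) {
    expect_equal(mean(zg[grp == g]), 0, tolerance = 1e-12)
    expect_equal(sd(zg[grp == g]), 1, tolerance = 1e-12)
  }
})

test_that("OLS recovers an exact linear relation and flags collinearity", {
  x <- rnorm(50)
  fit <- ols_fit(2 * x, x)
  expect_equal(fit$beta, 2, tolerance = 1e-10)
  expect_lt(fit$se, 1e-10)
  expect_equal(fit$method_tag, "OLS")
  expect_true(fit$ci_low <= fit$beta && fit$beta <= fit$ci_high)

  covs <- data.frame(a = x, b = 2 * x)
  expect_error(ols_fit(rnorm(50), rnorm(50), covs), "collinear.*b")
})

test_that("OLS bias under confounding matches the omitted-variable oracle", {
  # closed form: slope = causal + b_cy * cov(z, C) with
  # cov(z, C) = b_cx / sd(log exposure)
  cfg <- cohort_config(n_individuals = 50000, causal_beta = 0.5,
                       confounder_beta_x = 0.15, confounder_beta_y = 2,
                       target_r2 = 0.053, seed = 5)
  co <- simulate_cohort(cfg)
  z <- standardize_log_exposure(co$exposure)
  fit <- ols_fit(co$sbp, z)
  sd_logx <- sqrt(solve_instrument_beta(0.053, 0.31, 0.15, 0.25)^2 *
                    2 * 0.31 * 0.69 + 0.15^2 + 0.25^2)
  expected <- 0.5 + 2 * 0.15 / sd_logx
  expect_lt(abs(fit$beta - expected), 3 * fit$se)
})

test_that("2SLS equals the brute-force Wald ratio with one instrument", {
  for (s in 1:10) {
    co <- quick_cohort(s, n = 400, causal_beta = 0.5)
    z <- standardize_log_exposure(co$exposure)
    fit <- suppressWarnings(tsls_fit(co$sbp, z, co$genotype))
    expect_equal(fit$estimate$beta, wald_oracle(co$genotype, z, co$sbp),
                 tolerance = 1e-10)
  }
})

test_that("2SLS collapses to OLS when the exposure is the instrument", {
  co <- quick_cohort(2, n = 300)
  g <- as.numeric(co$genotype)
  fit_iv <- tsls_fit(co$sbp, g, g)
  fit_ols <- ols_fit(co$sbp, g)
  expect_equal(fit_iv$estimate$beta, fit_ols$beta, tolerance = 1e-10)
  expect_equal(fit_iv$estimate$se, fit_ols$se, tolerance = 1e-10)
  d <- dwh_test(co$sbp, g, g)
  expect_equal(d$statistic, 0)
  expect_equal(d$p_value, 1)
})

test_that("covariate adjustment obeys the Frisch-Waugh property", {
  co <- quick_cohort(9, n = 800,
                     ancestry_strata = list(c(0.6, 0.1, 4), c(0.4, -0.1, -4)))
  z <- standardize_log_exposure(co$exposure)
  covs <- data.frame(pc1 = co$pc1, sex = co$sex)
  fit <- suppressWarnings(tsls_fit(co$sbp, z, co$genotype, covs))

  W <- cbind(1, model.matrix(~ pc1 + sex, covs)[, -1])
  resid_on <- function(v) drop(v - W %*% solve(crossprod(W), crossprod(W, v)))
  yr <- resid_on(co$sbp)
  zr <- resid_on(z)
  gr <- resid_on(as.numeric(co$genotype))
  expect_equal(fit$estimate$beta, wald_oracle(gr, zr, yr), tolerance = 1e-8)

  fo <- ols_fit(co$sbp, z, covs)
  ols_fw <- lm(yr ~ zr)
  expect_equal(fo$beta, unname(coef(ols_fw)[2]), tolerance = 1e-8)
})

test_that("weak instruments trigger a warning, constant instruments an error", {
  co <- quick_cohort(3, n = 200, instrument_beta = 0.001)
  z <- standardize_log_exposure(co$exposure)
  expect_warning(tsls_fit(co$sbp, z, co$genotype), "weak instrument")
  expect_error(tsls_fit(co$sbp, z, rep(1, 200)), "constant")
})

test_that("DWH statistic is invariant to affine rescaling of the exposure", {
  co <- quick_cohort(4, n = 600, confounder_beta_y = 3)
  z <- standardize_log_exposure(co$exposure)
  d1 <- dwh_test(co$sbp, z, co$genotype)
  d2 <- dwh_test(co$sbp, 5 + 2.7 * z, co$genotype)
  expect_equal(d1$statistic, d2$statistic, tolerance = 1e-9)
  expect_equal(d1$p_value, d2$p_value, tolerance = 1e-9)
})

test_that("OLS exceeds 2SLS on average under positive confounding", {
  est <- t(sapply(1:500, function(s) {
    co <- simulate_cohort(cohort_config(
      n_individuals = 600, causal_beta = 0, target_r2 = 0.1,
      confounder_beta_x = 0.15, confounder_beta_y = 3, seed = s))
    z <- standardize_log_exposure(co$exposure)
    c(ols = ols_fit(co$sbp, z)$beta,
      tsls = suppressWarnings(tsls_fit(co$sbp, z, co$genotype))$estimate$beta)
  }))
  d <- est[, "ols"] - est[, "tsls"]
  expect_gt(mean(d), 3 * sd(d) / sqrt(length(d)))
})

test_that("weakening the instrument pulls 2SLS toward the OLS estimate", {
  # the just-identified IV estimator is a ratio with no finite mean, so the
  # center of its sampling distribution is tracked by the median: under
  # positive confounding (OLS limit ~ +7.7 here) it rises monotonically from
  # ~0 toward the observational slope as the instrument weakens
  betas <- c(0.10, 0.02, 0.005)
  reps <- 400
  est <- sapply(betas, function(b) {
    sapply(1:reps, function(s) {
      co <- simulate_cohort(cohort_config(
        n_individuals = 2000, causal_beta = 0, instrument_beta = b,
        confounder_beta_x = 0.3, confounder_beta_y = 10, seed = s))
      z <- standardize_log_exposure(co$exposure)
      suppressWarnings(tsls_fit(co$sbp, z, co$genotype))$estimate$beta
    })
  })
  m <- apply(est, 2, stats::median)
  expect_true(all(diff(m) > 0))
  expect_lt(abs(m[1]), 0.5)  # strong instrument: centred at the causal null
  expect_gt(m[3], 4)         # nearly irrelevant instrument: near the OLS slope
})

test_that("balance test calibrates under the null and detects stratification", {
  co <- quick_cohort(21, n = 2500,
                     ancestry_strata = list(c(0.6, 0.12, 0), c(0.4, -0.18, 0)))
  res <- covariate_balance(co$genotype, co$skin,
                           ancestry = data.frame(pc1 = co$pc1))
  expect_lt(res$p_unadjusted, 0.001)
  expect_gt(res$p_adjusted, 0.05)

  const <- covariate_balance(co$genotype, rep(1, nrow(co)))
  expect_equal(const$p_unadjusted, 1)

  # null: covariate independent of genotype; rejection rate near alpha
  rej <- sapply(1:100, function(s) {
    coh <- quick_cohort(1000 + s, n = 300)
    covariate_balance(coh$genotype, rnorm(300))$p_unadjusted < 0.05
  })
  expect_gte(mean(rej), 0.005)
  expect_lte(mean(rej), 0.12)
})

test_that("empty genotype classes collapse with a warning", {
  g <- factor(c(rep(0, 40), rep(1, 40)), levels = c(0, 1, 2))
  x <- rnorm(80)
  expect_warning(res <- covariate_balance(g, x), "collapsing")
  expect_true(res$p_unadjusted >= 0 && res$p_unadjusted <= 1)
})
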