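#' Harmonize summary statistics to the exposure-increasing allele
#'
#' Re-orients every SNP record so its effect allele is the
#' exposure-increasing allele: records with a negative exposure beta have
#' effect/other alleles swapped and BOTH betas negated; SEs are unchanged.
#' Records with a zero exposure beta are excluded (their orientation is
#' undefined) with a message. Palindromic records (A/T or G/C allele pairs,
#' whose strand cannot be resolved from alleles alone) are flagged in a
#' `palindromic` column and retained.
#'
#' @param panel A `summary_panel` data frame (see
#'   [simulate_two_sample_summary()] or [read_panel_tsv()]).
#' @return The harmonized panel, with logical columns `flipped` and
#'   `palindromic` added; every `beta_exp` is positive.
#' @export
harmonize <- function(panel) {
  panel <- as_summary_panel(panel)
  zero <- panel$beta_exp == 0
  if (any(zero)) {
    message(sprintf("excluding %d record(s) with zero exposure beta (orientation undefined): %s",
                    sum(zero), paste(panel$snp[zero], collapse = ", ")))
    panel <- panel[!zero, , drop = FALSE]
  }
  flip <- panel$beta_exp < 0
  if (any(flip)) {
    tmp <- panel$effect_allele[flip]
    panel$effect_allele[flip] <- panel$other_allele[flip]
    panel$other_allele[flip] <- tmp
    panel$beta_exp[flip] <- -panel$beta_exp[flip]
    panel$beta_out[flip] <- -panel$beta_out[flip]
  }
  pal <- paste0(pmin(panel$effect_allele, panel$other_allele),
                pmax(panel$effect_allele, panel$other_allele)) %in% c("AT", "CG")
  if (any(pal)) {
    message(sprintf("%d palindromic record(s) retained (flagged): %s",
                    sum(pal), paste(panel$snp[pal], collapse = ", ")))
  }
  panel$flipped <- flip
  panel$palindromic <- pal
  attr(panel, "harmonized") <- TRUE
  panel
}

as_summary_panel <- function(panel) {
  need <- c("snp", "effect_allele", "other_allele",
            "beta_exp", "se_exp", "beta_out", "se_out")
  miss <- setdiff(need, names(panel))
  if (length(miss)) {
    stop("summary panel is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(panel$se_exp <= 0) || any(panel$se_out <= 0)) {
    stop("summary panel SEs must be > 0", call. = FALSE)
  }
  if (!inherits(panel, "summary_panel")) {
    class(panel) <- c("summary_panel", class(panel))
  }
  panel
}

#' Fixed-effects meta-analysis with inverse-variance weights
#'
#' Pools per-SNP (or per-study) effects with weights `w_i = 1/se_i^2`:
#' pooled beta is the weighted mean, pooled SE is `(sum w)^{-1/2}`, and
#' heterogeneity is summarized by Cochran's Q, its chi-squared p-value on
#' k - 1 df, and `I2 = max(0, (Q - df)/Q) * 100` percent.
#'
#' @param betas Effect estimates.
#' @param ses Matched standard errors (> 0).
#' @return A list of class `meta_result`: `pooled_beta`, `pooled_se`,
#'   `ci_low`, `ci_high`, `p_value`, `q_statistic`, `df`, `i2` (percent),
#'   `p_heterogeneity`, `k`.
#' @export
fixed_effects_meta <- function(betas, ses) {
  k <- length(betas)
  if (k == 0) stop("no effects to pool", call. = FALSE)
  stopifnot(length(ses) == k)
  if (any(ses <= 0)) stop("all SEs must be > 0", call. = FALSE)
  w <- 1 / ses^2
  pooled <- sum(w * betas) / sum(w)
  pooled_se <- sqrt(1 / sum(w))
  if (k == 1) {
    message("single study: heterogeneity undefined; Q = 0, I2 reported as 0")
    q <- 0
    df <- 0L
    p_het <- NA_real_
  } else {
    q <- sum(w * (betas - pooled)^2)
    df <- k - 1L
    p_het <- pchisq(q, df, lower.tail = FALSE)
  }
  i2 <- if (q > df && q > 0) (q - df) / q * 100 else 0
  z <- qnorm(0.975)
  structure(
    list(pooled_beta = pooled, pooled_se = pooled_se,
         ci_low = pooled - z * pooled_se, ci_high = pooled + z * pooled_se,
         p_value = 2 * pnorm(-abs(pooled / pooled_se)),
         q_statistic = q, df = df, i2 = i2, p_heterogeneity = p_het, k = k),
    class = "meta_result"
  )
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("Fixed-effects meta-analysis (k = %d)\n", x$k))
  cat(sprintf("  pooled = %.4f (95%% CI %.4f, %.4f), se = %.4f\n",
              x$pooled_beta, x$ci_low, x$ci_high, x$pooled_se))
  cat(sprintf("  Q = %.3f on %d df (p = %.3g), I2 = %.1f%%\n",
              x$q_statistic, x$df, x$p_heterogeneity, x$i2))
  invisible(x)
}

new_mr_estimate <- function(beta, se, n_snps, method_tag) {
  z <- qnorm(0.975)
  structure(
    list(beta = beta, se = se,
         ci_low = beta - z * se, ci_high = beta + z * se,
         p_value = 2 * pnorm(-abs(beta / se)),
         n_snps = n_snps, method_tag = method_tag),
    class = "mr_estimate"
  )
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s causal estimate (%d SNP%s)\n", x$method_tag, x$n_snps,
              if (x$n_snps > 1) "s" else ""))
  cat(sprintf("  beta = %.3f mm Hg/SD (95%% CI %.3f, %.3f), se = %.3f, p = %.3g\n",
              x$beta, x$ci_low, x$ci_high, x$se, x$p_value))
  invisible(x)
}

#' Single-SNP inverse-variance-weighted (Wald ratio) estimate
#'
#' For one instrument the causal estimate is the ratio of the per-allele
#' outcome effect Y to the per-allele exposure effect X, with
#' `se = se_out / |X|` (first-order: the exposure SE is ignored, as is
#' conventional for strong instruments). The 95% CI uses the 1.96 normal
#' multiplier. An optional delta-method SE incorporating the exposure SE is
#' available.
#'
#' @param record A one-row `summary_panel` (or list with `beta_exp`,
#'   `beta_out`, `se_out`, optionally `se_exp`).
#' @param delta_se If `TRUE`, use the second-order delta-method SE
#'   `sqrt(se_out^2/X^2 + Y^2 se_exp^2 / X^4)` instead of `se_out/|X|`.
#' @return An `mr_estimate` with `method_tag = "IVW_single"`.
#' @export
ivw_single <- function(record, delta_se = FALSE) {
  x <- record$beta_exp
  y <- record$beta_out
  sy <- record$se_out
  stopifnot(length(x) == 1, length(y) == 1, length(sy) == 1)
  if (x == 0) stop("beta_exp is zero: Wald ratio undefined", call. = FALSE)
  beta <- y / x
  se <- if (delta_se) {
    sx <- record$se_exp
    sqrt(sy^2 / x^2 + y^2 * sx^2 / x^4)
  } else {
    sy / abs(x)
  }
  new_mr_estimate(beta, se, 1L, "IVW_single")
}

#' Multi-SNP inverse-variance-weighted estimate
#'
#' Combines the per-SNP Wald ratios in a fixed-effects meta-analysis with
#' weights inverse to the SNP-outcome variances:
#' `beta = sum(X_k Y_k / s_k^2) / sum(X_k^2 / s_k^2)` with
#' `se = (sum(X_k^2 / s_k^2))^{-1/2}` — algebraically identical to
#' [fixed_effects_meta()] applied to ratios `Y_k/X_k` with SEs
#' `s_k/|X_k|`, and to weighted regression of Y on X through the origin.
#'
#' @param panel A harmonized `summary_panel` with at least 2 SNPs.
#' @return An `mr_estimate` with `method_tag = "IVW_multi"`.
#' @export
ivw_multi <- function(panel) {
  panel <- as_summary_panel(panel)
  k <- nrow(panel)
  if (k < 2) {
    stop("ivw_multi needs at least 2 SNPs; use ivw_single for one instrument",
         call. = FALSE)
  }
  if (any(panel$beta_exp == 0)) {
    stop("beta_exp is zero for some record(s); harmonize() excludes these",
         call. = FALSE)
  }
  w <- 1 / panel$se_out^2
  denom <- sum(panel$beta_exp^2 * w)
  beta <- sum(panel$beta_exp * panel$beta_out * w) / denom
  se <- sqrt(1 / denom)
  new_mr_estimate(beta, se, k, "IVW_multi")
}

# Closed-form weighted least squares of y on x with intercept.
# Returns coefficients and the classical (dispersion-estimated) vcov.
wls_line <- function(x, y, w) {
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  swxx <- sum(w * x^2); swxy <- sum(w * x * y)
  det <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / det
  intercept <- (swy - slope * swx) / sw
  r <- y - intercept - slope * x
  df <- length(x) - 2
  disp <- sum(w * r^2) / df
  var_slope <- disp * sw / det
  var_int <- disp * swxx / det
  list(intercept = intercept, slope = slope,
       se_intercept = sqrt(var_int), se_slope = sqrt(var_slope), df = df)
}

#' MR-Egger regression with percentile-bootstrap confidence intervals
#'
#' Weighted least squares of the SNP-outcome betas on the SNP-exposure betas
#' WITH an intercept, weighting by the inverse variance of the SNP-outcome
#' associations. Under the InSIDE assumption the slope is a valid causal
#' estimate even under directional pleiotropy, and the intercept estimates
#' the average direct (pleiotropic) effect per allele. Because the intercept
#' is meaningful only when all effects refer to exposure-increasing alleles,
#' the panel must be harmonized first.
#'
#' Percentile-bootstrap 95% CIs are computed by resampling the SNP records
#' with replacement (`scheme = "nonparametric"`, the default) or by redrawing
#' each outcome beta from a normal distribution centred on its fitted value
#' with SD `se_out` (`scheme = "parametric"`), refitting, and taking the
#' 2.5/97.5 percentiles of each coefficient. Analytic weighted-least-squares
#' t intervals are also reported.
#'
#' @param panel A harmonized `summary_panel` with at least 3 SNPs and
#'   non-degenerate exposure betas.
#' @param n_boot Number of bootstrap iterations (default 10000).
#' @param seed Integer seed for the bootstrap; results are deterministic
#'   given the seed.
#' @param scheme Bootstrap scheme, `"nonparametric"` or `"parametric"`.
#' @return A list of class `egger_result`: `intercept`, `slope`, their
#'   analytic SEs and p-values, bootstrap percentile CIs `intercept_ci` /
#'   `slope_ci`, analytic t CIs `intercept_ci_analytic` /
#'   `slope_ci_analytic`, `n_boot`, `seed`, `scheme`, `n_snps`.
#' @export
egger_regression <- function(panel, n_boot = 10000, seed = 1L,
                             scheme = c("nonparametric", "parametric")) {
  scheme <- match.arg(scheme)
  panel <- as_summary_panel(panel)
  k <- nrow(panel)
  if (k < 3) stop("MR-Egger needs at least 3 SNPs", call. = FALSE)
  if (!isTRUE(attr(panel, "harmonized")) && any(panel$beta_exp < 0)) {
    stop("panel must be harmonized before MR-Egger (orientation-sensitive)",
         call. = FALSE)
  }
  if (n_boot < 1) stop("n_boot must be >= 1", call. = FALSE)
  x <- panel$beta_exp
  y <- panel$beta_out
  if (sd(x) == 0) stop("degenerate exposure betas (all equal): slope unidentified",
                       call. = FALSE)
  w <- 1 / panel$se_out^2
  fit <- wls_line(x, y, w)

  boot <- with_seed(seed, {
    coefs <- matrix(NA_real_, n_boot, 2)
    if (scheme == "nonparametric") {
      b <- 0L
      while (b < n_boot) {
        idx <- sample.int(k, k, replace = TRUE)
        if (sd(x[idx]) == 0) next  # slope unidentified in this resample
        b <- b + 1L
        f <- wls_line(x[idx], y[idx], w[idx])
        coefs[b, ] <- c(f$intercept, f$slope)
      }
    } else {
      mu <- fit$intercept + fit$slope * x
      for (b in seq_len(n_boot)) {
        yb <- rnorm(k, mu, panel$se_out)
        f <- wls_line(x, yb, w)
        coefs[b, ] <- c(f$intercept, f$slope)
      }
    }
    coefs
  })
  ci_int <- unname(quantile(boot[, 1], c(0.025, 0.975)))
  ci_slo <- unname(quantile(boot[, 2], c(0.025, 0.975)))
  tmult <- qt(0.975, fit$df)
  structure(
    list(intercept = fit$intercept, slope = fit$slope,
         intercept_se = fit$se_intercept, slope_se = fit$se_slope,
         intercept_p = 2 * pt(-abs(fit$intercept / fit$se_intercept), fit$df),
         slope_p = 2 * pt(-abs(fit$slope / fit$se_slope), fit$df),
         intercept_ci = ci_int, slope_ci = ci_slo,
         intercept_ci_analytic = fit$intercept + c(-1, 1) * tmult * fit$se_intercept,
         slope_ci_analytic = fit$slope + c(-1, 1) * tmult * fit$se_slope,
         n_boot = as.integer(n_boot), seed = as.integer(seed),
         scheme = scheme, n_snps = k),
    class = "egger_result"
  )
}

#' @export
print.egger_result <- function(x, ...) {
  cat(sprintf("MR-Egger regression (%d SNPs; %s bootstrap, %d iterations)\n",
              x$n_snps, x$scheme, x$n_boot))
  cat(sprintf("  slope     = %.3f mm Hg/SD (95%% bootstrap CI %.3f, %.3f)\n",
              x$slope, x$slope_ci[1], x$slope_ci[2]))
  cat(sprintf("  intercept = %.3f mm Hg/allele (95%% bootstrap CI %.3f, %.3f)\n",
              x$intercept, x$intercept_ci[1], x$intercept_ci[2]))
  invisible(x)
}
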