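#' Log-transform and standardize an exposure
#'
#' Circulating homocysteine is right-skewed, so the analysis scale is
#' natural-log concentration expressed in SD units. The sample SD (n - 1
#' denominator) is used. When `group` is supplied, centering and scaling are
#' done within each group (the convention of sex-specific SD units used by
#' homocysteine GWAS); the default is overall standardization.
#'
#' @param exposure_raw Positive concentrations (umol/L).
#' @param group Optional grouping labels (e.g. sex) for group-wise
#'   standardization.
#' @return Numeric vector with mean 0 and SD 1 (overall, or within each
#'   group).
#' @examples
#' standardize_log_exposure(c(1, exp(1), exp(2)))  # -1, 0, 1
#' @export
standardize_log_exposure <- function(exposure_raw, group = NULL) {
  bad <- which(!is.finite(exposure_raw) | exposure_raw <= 0)
  if (length(bad)) {
    stop(sprintf(
      "exposure must be positive and finite; offending record(s): %s",
      paste(head(bad, 5L), collapse = ", ")
    ), call. = FALSE)
  }
  lx <- log(exposure_raw)
  zscore <- function(v) {
    s <- sd(v)
    if (!is.finite(s) || s == 0) {
      stop("exposure is constant (zero SD); standardization undefined",
           call. = FALSE)
    }
    (v - mean(v)) / s
  }
  if (is.null(group)) {
    return(zscore(lx))
  }
  stopifnot(length(group) == length(lx))
  out <- numeric(length(lx))
  for (g in unique(group)) {
    i <- which(group == g)
    out[i] <- zscore(lx[i])
  }
  out
}

new_regression_result <- function(beta, se, n, df, method_tag,
                                  covariate_set = character(0),
                                  normal_ci = FALSE) {
  mult <- if (normal_ci) qnorm(0.975) else qt(0.975, df)
  p <- if (normal_ci) {
    2 * pnorm(-abs(beta / se))
  } else {
    2 * pt(-abs(beta / se), df)
  }
  structure(
    list(beta = beta, se = se,
         ci_low = beta - mult * se, ci_high = beta + mult * se,
         p_value = p, n = n, method_tag = method_tag,
         covariate_set = covariate_set),
    class = "mr_regression"
  )
}

#' @export
print.mr_regression <- function(x, ...) {
  cat(sprintf("%s estimate (n = %d%s)\n", x$method_tag, x$n,
              if (length(x$covariate_set)) {
                paste0("; adjusted for ", paste(x$covariate_set, collapse = ", "))
              } else "; crude"))
  cat(sprintf("  beta = %.3f mm Hg/SD (95%% CI %.3f, %.3f), se = %.3f, p = %.3g\n",
              x$beta, x$ci_low, x$ci_high, x$se, x$p_value))
  invisible(x)
}

# Build a covariate model matrix (no intercept column), checking rank.
covariate_matrix <- function(covariates, n) {
  if (is.null(covariates) || (is.data.frame(covariates) && ncol(covariates) == 0)) {
    return(matrix(numeric(0), nrow = n, ncol = 0))
  }
  if (is.vector(covariates) && !is.list(covariates)) {
    covariates <- data.frame(covariate = covariates)
  }
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == n)
  mm <- model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
  mm
}

check_full_rank <- function(X, context) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("rank-deficient design in %s; collinear column(s): %s",
                 context, paste(dropped, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Ordinary least-squares regression of blood pressure on exposure
#'
#' The conventional observational estimate: outcome (mm Hg) regressed on the
#' standardized log exposure with optional covariate adjustment. Classical
#' homoskedastic SEs; 95% CI from the t distribution with residual degrees of
#' freedom.
#'
#' @param outcome Numeric outcome, mm Hg.
#' @param exposure_sd Exposure in SD units (see [standardize_log_exposure()]).
#' @param covariates Optional data frame (or vector) of adjustment
#'   covariates; factors are expanded to dummies.
#' @return An object of class `mr_regression` for the exposure coefficient.
#' @export
ols_fit <- function(outcome, exposure_sd, covariates = NULL) {
  n <- length(outcome)
  stopifnot(length(exposure_sd) == n)
  if (anyNA(outcome) || anyNA(exposure_sd)) {
    stop("missing values are not allowed; apply complete-case filtering first",
         call. = FALSE)
  }
  W <- covariate_matrix(covariates, n)
  X <- cbind(`(Intercept)` = 1, exposure = exposure_sd, W)
  if (n <= ncol(X)) stop("n must exceed the number of parameters", call. = FALSE)
  check_full_rank(X, "ols_fit")
  fit <- lm.fit(X, outcome)
  df <- n - ncol(X)
  sigma2 <- sum(fit$residuals^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * XtXinv[2, 2])
  new_regression_result(unname(fit$coefficients["exposure"]), se, n, df,
                        "OLS", colnames(W))
}

#' Two-stage least-squares (instrumental-variable) regression
#'
#' Mendelian randomization estimate from individual-level data. Stage one
#' regresses the standardized log exposure on the genotype dosage (plus
#' covariates); stage two regresses the outcome on the stage-one fitted
#' values (plus the same covariates). The coefficient SE uses the
#' instrumental-variable variance formula with residuals computed from the
#' ORIGINAL exposure, not the stage-two plug-in residuals. First-stage
#' diagnostics report the instrument's partial F and partial R-squared; a
#' partial F below 10 triggers a weak-instrument warning.
#'
#' @inheritParams ols_fit
#' @param instrument Genotype dosage (0/1/2 copies of the effect allele), or
#'   any single numeric instrument.
#' @param robust If `TRUE`, heteroskedasticity-robust (HC0 sandwich) SEs are
#'   used instead of the classical IV formula.
#' @return A list of class `tsls_fit` with elements `estimate`
#'   (`mr_regression`, `method_tag = "2SLS"`) and `diagnostics` (class
#'   `first_stage_diagnostics`: `f_statistic`, `r2`, `p_value`).
#' @export
tsls_fit <- function(outcome, exposure_sd, instrument, covariates = NULL,
                     robust = FALSE) {
  n <- length(outcome)
  stopifnot(length(exposure_sd) == n, length(instrument) == n)
  if (anyNA(outcome) || anyNA(exposure_sd) || anyNA(instrument)) {
    stop("missing values are not allowed; apply complete-case filtering first",
         call. = FALSE)
  }
  if (var(instrument) == 0) {
    stop("instrument is constant; IV estimation undefined", call. = FALSE)
  }
  W <- covariate_matrix(covariates, n)
  X1 <- cbind(`(Intercept)` = 1, instrument = instrument, W)
  check_full_rank(X1, "tsls_fit first stage")

  s1 <- lm.fit(X1, exposure_sd)
  xhat <- exposure_sd - s1$residuals

  # partial F / R2 of the instrument given the covariates
  X0 <- cbind(`(Intercept)` = 1, W)
  s0 <- lm.fit(X0, exposure_sd)
  rss1 <- sum(s1$residuals^2)
  rss0 <- sum(s0$residuals^2)
  df1 <- n - ncol(X1)
  f_stat <- (rss0 - rss1) / (rss1 / df1)
  r2 <- (rss0 - rss1) / rss0
  diag1 <- structure(
    list(f_statistic = f_stat, r2 = r2,
         p_value = pf(f_stat, 1, df1, lower.tail = FALSE)),
    class = "first_stage_diagnostics"
  )
  if (f_stat < 10) {
    warning(sprintf("weak instrument: first-stage partial F = %.2f < 10", f_stat),
            call. = FALSE)
  }

  Xh <- cbind(`(Intercept)` = 1, exposure = xhat, W)
  check_full_rank(Xh, "tsls_fit second stage")
  s2 <- lm.fit(Xh, outcome)
  b <- s2$coefficients

  # IV residuals with the original exposure
  Xs <- cbind(`(Intercept)` = 1, exposure = exposure_sd, W)
  e <- outcome - drop(Xs %*% b)
  p <- ncol(Xh)
  df <- n - p
  XhtXhinv <- chol2inv(chol(crossprod(Xh)))
  if (robust) {
    meat <- crossprod(Xh * e, Xh)
    V <- XhtXhinv %*% meat %*% XhtXhinv
  } else {
    sigma2 <- sum(e^2) / df
    V <- sigma2 * XhtXhinv
  }
  se <- sqrt(V[2, 2])
  est <- new_regression_result(unname(b["exposure"]), se, n, df, "2SLS",
                               colnames(W))
  structure(list(estimate = est, diagnostics = diag1), class = "tsls_fit")
}

#' @export
print.tsls_fit <- function(x, ...) {
  print(x$estimate)
  cat(sprintf("  first stage: partial F = %.1f, R2 = %.4f, p = %.3g\n",
              x$diagnostics$f_statistic, x$diagnostics$r2,
              x$diagnostics$p_value))
  invisible(x)
}

#' Durbin-Wu-Hausman test of exposure endogeneity
#'
#' Compares the OLS and 2SLS estimands via the control-function augmented
#' regression: the exposure is regressed on instrument plus covariates, the
#' first-stage residual is added to the outcome OLS model, and its
#' coefficient is tested against zero. The squared t statistic is reported
#' with (1, n - p) degrees of freedom. This form is asymptotically equivalent
#' to the classical contrast (delta-beta squared over delta-variance)
#' statistic but numerically stable when the variance difference is near
#' zero. Rejection suggests the observational (OLS) estimate is confounded.
#'
#' @inheritParams tsls_fit
#' @return A list of class `dwh_result`: `statistic`, `df` (numerator and
#'   denominator), `p_value`.
#' @export
dwh_test <- function(outcome, exposure_sd, instrument, covariates = NULL) {
  n <- length(outcome)
  stopifnot(length(exposure_sd) == n, length(instrument) == n)
  if (var(instrument) == 0) {
    stop("instrument is constant; IV estimation undefined", call. = FALSE)
  }
  W <- covariate_matrix(covariates, n)
  X1 <- cbind(1, instrument, W)
  v <- lm.fit(X1, exposure_sd)$residuals

  Xa <- cbind(`(Intercept)` = 1, exposure = exposure_sd, W)
  if (var(v) < 1e-12 * max(var(exposure_sd), 1)) {
    # exposure fully determined by instrument + covariates: estimators coincide
    return(structure(list(statistic = 0, df = c(1L, n - ncol(Xa) - 1L),
                          p_value = 1), class = "dwh_result"))
  }
  Xa <- cbind(Xa, fs_resid = v)
  check_full_rank(Xa, "dwh_test augmented regression")
  fit <- lm.fit(Xa, outcome)
  df <- n - ncol(Xa)
  sigma2 <- sum(fit$residuals^2) / df
  Vinv <- chol2inv(chol(crossprod(Xa)))
  tval <- fit$coefficients["fs_resid"] / sqrt(sigma2 * Vinv[ncol(Xa), ncol(Xa)])
  stat <- unname(tval^2)
  structure(
    list(statistic = stat, df = c(1L, df),
         p_value = pf(stat, 1, df, lower.tail = FALSE)),
    class = "dwh_result"
  )
}

#' @export
print.dwh_result <- function(x, ...) {
  cat(sprintf("Durbin-Wu-Hausman test: F = %.3f on (%d, %d) df, p = %.3g\n",
              x$statistic, x$df[1], x$df[2], x$p_value))
  invisible(x)
}

multinom_lrt_p <- function(geno, rhs_full, rhs_null, data) {
  full <- nnet::multinom(as.formula(paste("geno ~", rhs_full)), data = data,
                         trace = FALSE, maxit = 500)
  null <- nnet::multinom(as.formula(paste("geno ~", rhs_null)), data = data,
                         trace = FALSE, maxit = 500)
  stat <- null$deviance - full$deviance
  df <- length(coef(full)) - length(coef(null))
  if (df <= 0) return(1)
  pchisq(max(stat, 0), df, lower.tail = FALSE)
}

#' Genotype-covariate balance test
#'
#' Tests whether the genotype distribution differs across covariate levels,
#' the standard check that a genetic instrument is independent of potential
#' confounders. The genotype class (CC/CT/TT, i.e. dosage 0/1/2) is modelled
#' as a multinomial outcome of the covariate; the heterogeneity p-value is a
#' likelihood-ratio test of the covariate's coefficients. When ancestry
#' columns are supplied the adjusted p-value is computed the same way with
#' the ancestry terms in both models, which removes spurious associations due
#' to population stratification.
#'
#' @param genotype Dosage vector (0/1/2) or factor of genotype classes.
#' @param covariate A single covariate, categorical or numeric.
#' @param ancestry Optional data frame (or vector) of ancestry covariates
#'   (principal-component scores).
#' @param name Label for the covariate in the result.
#' @return A list of class `balance_result`: `covariate`, `p_unadjusted`,
#'   `p_adjusted` (`NA` when no ancestry supplied).
#' @export
covariate_balance <- function(genotype, covariate, ancestry = NULL,
                              name = deparse(substitute(covariate))) {
  geno <- if (is.factor(genotype)) genotype else factor(genotype)
  if (nlevels(geno) < 2) {
    stop("genotype must have at least 2 observed classes", call. = FALSE)
  }
  tab <- table(geno)
  if (any(tab == 0)) {
    warning("empty genotype class; collapsing to a 2-class model", call. = FALSE)
    geno <- droplevels(geno)
    if (nlevels(geno) > 2) {
      small <- names(sort(tab[tab > 0]))[1]
      levels(geno)[levels(geno) == small] <- levels(geno)[levels(geno) != small][1]
    }
  }
  cov_const <- if (is.numeric(covariate)) {
    var(covariate) == 0
  } else {
    length(unique(covariate)) < 2
  }
  if (cov_const) {
    return(structure(list(covariate = name, p_unadjusted = 1,
                          p_adjusted = if (is.null(ancestry)) NA_real_ else 1),
                     class = "balance_result"))
  }
  dat <- data.frame(geno = geno, covariate = covariate)
  p_un <- multinom_lrt_p(geno, "covariate", "1", dat)
  p_adj <- NA_real_
  if (!is.null(ancestry)) {
    A <- as.data.frame(ancestry)
    if (!ncol(A)) A <- data.frame(ancestry = unlist(ancestry))
    names(A) <- paste0("anc_", seq_len(ncol(A)))
    dat <- cbind(dat, A)
    anc_rhs <- paste(names(A), collapse = " + ")
    p_adj <- multinom_lrt_p(geno, paste("covariate +", anc_rhs), anc_rhs, dat)
  }
  structure(list(covariate = name, p_unadjusted = p_un, p_adjusted = p_adj),
            class = "balance_result")
}

#' @export
print.balance_result <- function(x, ...) {
  cat(sprintf("Genotype balance for '%s': p = %.3g (unadjusted)", x$covariate,
              x$p_unadjusted))
  if (!is.na(x$p_adjusted)) cat(sprintf(", p = %.3g (ancestry-adjusted)", x$p_adjusted))
  cat("\n")
  invisible(x)
}
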