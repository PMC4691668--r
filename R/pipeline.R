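#' Configure a full MR analysis run
#'
#' Bundles everything [run_pipeline()] needs: the mode, input paths (or
#' generator configs in `simulate` mode), outcome selection, adjustment
#' presets, estimator switches and the seed. Adjustment presets map to
#' covariate lists the way an epidemiological model ladder does:
#' `crude` (no covariates), `pca` (ancestry principal-component scores),
#' `sociodemographic` (sex, skin colour), `full` (both sets). OLS models use
#' the sociodemographic/full rungs; 2SLS models use crude/pca, since genetic
#' instruments need no lifestyle adjustment but can be confounded by
#' ancestry.
#'
#' @param mode One of `"simulate"`, `"onesample"`, `"twosample"`, `"both"`.
#'   In `simulate` mode inputs are generated from `cohort_config` /
#'   `panel_config`; otherwise the file paths must exist.
#' @param cohort_file Path to a cohort TSV (non-simulate one-sample modes).
#' @param panel_files Named list/vector of summary-panel TSV paths, names
#'   among `"sbp"`, `"dbp"` (non-simulate two-sample modes).
#' @param outcome `"both"` (default), `"sbp"` or `"dbp"`.
#' @param adjustments Character vector of preset names to run (default
#'   `c("crude", "pca", "sociodemographic", "full")`).
#' @param by_sex Also run one-sample models within each sex stratum
#'   (subsetting, not interaction terms).
#' @param estimators Which analysis blocks to run; subset of
#'   `c("ols", "tsls", "dwh", "balance", "meta", "ivw", "egger")`.
#' @param single_snp SNP id to use for the single-SNP IVW estimate; default
#'   the panel SNP with the largest absolute exposure effect (the
#'   functional-variant convention).
#' @param n_boot Bootstrap iterations for MR-Egger CIs.
#' @param seed Integer seed; required because simulation and the Egger
#'   bootstrap are stochastic.
#' @param cohort_config A [cohort_config()] for simulate mode.
#' @param panel_config A [two_sample_config()] for simulate mode.
#' @param output_dir Directory for [render_report()] outputs.
#' @return An `analysis_config` object.
#' @export
analysis_config <- function(mode = c("simulate", "onesample", "twosample", "both"),
                            cohort_file = NULL,
                            panel_files = NULL,
                            outcome = c("both", "sbp", "dbp"),
                            adjustments = c("crude", "pca",
                                            "sociodemographic", "full"),
                            by_sex = FALSE,
                            estimators = c("ols", "tsls", "dwh", "balance",
                                           "meta", "ivw", "egger"),
                            single_snp = NULL,
                            n_boot = 10000,
                            seed = NULL,
                            cohort_config = NULL,
                            panel_config = NULL,
                            output_dir = "mr_output") {
  mode <- match.arg(mode)
  outcome <- match.arg(outcome)
  estimators <- match.arg(estimators, several.ok = TRUE)
  known <- c("crude", "pca", "sociodemographic", "full")
  if (!all(adjustments %in% known)) {
    stop_config("adjustments", paste("must be among", paste(known, collapse = ", ")))
  }
  if (is.null(seed)) {
    stop_config("seed", "a seed is required: simulation and the Egger bootstrap are stochastic")
  }
  if (mode %in% c("onesample", "both") && is.null(cohort_file)) {
    if (mode != "both" || is.null(cohort_config)) {
      stop_config("cohort_file", "required in non-simulate one-sample modes")
    }
  }
  if (!is.null(cohort_file) && !file.exists(cohort_file)) {
    stop_config("cohort_file", paste("file does not exist:", cohort_file))
  }
  if (mode %in% c("twosample", "both") && is.null(panel_files) &&
      is.null(panel_config)) {
    stop_config("panel_files", "required in non-simulate two-sample modes")
  }
  if (!is.null(panel_files)) {
    panel_files <- as.list(panel_files)
    if (is.null(names(panel_files)) ||
        !all(names(panel_files) %in% c("sbp", "dbp"))) {
      stop_config("panel_files", "must be named with outcomes 'sbp'/'dbp'")
    }
    ok <- vapply(panel_files, file.exists, logical(1))
    if (!all(ok)) {
      stop_config("panel_files", paste("file does not exist:",
                                       paste(unlist(panel_files)[!ok], collapse = ", ")))
    }
  }
  structure(
    list(mode = mode, cohort_file = cohort_file, panel_files = panel_files,
         outcome = outcome, adjustments = adjustments, by_sex = by_sex,
         estimators = estimators, single_snp = single_snp,
         n_boot = as.integer(n_boot), seed = as.integer(seed),
         cohort_config = cohort_config, panel_config = panel_config,
         output_dir = output_dir),
    class = "analysis_config"
  )
}

adjustment_columns <- function(preset, cohort) {
  pcs <- grep("^pc[0-9]+$", names(cohort), value = TRUE)
  socio <- intersect(c("sex", "skin"), names(cohort))
  switch(preset,
         crude = character(0),
         pca = pcs,
         sociodemographic = socio,
         full = c(socio, pcs))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full Mendelian randomization analysis plan
#'
#' Executes the enabled branches of the analysis plan — observational OLS
#' (crude and covariate-adjusted), one-sample 2SLS with first-stage
#' diagnostics and the Durbin-Wu-Hausman test (crude and ancestry-adjusted),
#' genotype-covariate balance checks, and the two-sample arm (fixed-effects
#' meta-analysis with I2, single- and multi-SNP IVW, MR-Egger with bootstrap
#' CIs) — and collects every result into a report. The run is deterministic:
#' identical config (and therefore seed) yields an identical report.
#'
#' @param config An [analysis_config()].
#' @return A list of class `mr_report` with elements `blocks` (named list of
#'   result blocks keyed by `outcome|method|adjustment|stratum`),
#'   `provenance` (config hash, seed, package version), `log` (one line per
#'   estimator with the n actually used) and `data` (the inputs, for
#'   rendering).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  blocks <- list()
  add_block <- function(outcome, method, adjustment, stratum, result) {
    key <- paste(outcome, method, adjustment, stratum, sep = "|")
    if (key %in% names(blocks)) {
      stop(sprintf("duplicate analysis block '%s'", key), call. = FALSE)
    }
    blocks[[key]] <<- list(outcome = outcome, method = method,
                           adjustment = adjustment, stratum = stratum,
                           result = result)
  }
  outcomes <- if (config$outcome == "both") c("sbp", "dbp") else config$outcome
  want <- function(e) e %in% config$estimators
  one_sample <- config$mode %in% c("simulate", "onesample", "both")
  two_sample <- config$mode %in% c("simulate", "twosample", "both")
  data_used <- list()

  if (one_sample) {
    cohort <- run_stage("load_cohort", {
      if (!is.null(config$cohort_file)) {
        read_cohort_tsv(config$cohort_file)
      } else {
        cc <- config$cohort_config %||% cohort_config(seed = config$seed)
        cc$seed <- config$seed
        simulate_cohort(cc)
      }
    })
    cohort <- cohort[complete.cases(as.data.frame(cohort)), , drop = FALSE]
    note("cohort loaded: n = %d complete cases", nrow(cohort))
    data_used$cohort <- cohort
    z <- run_stage("standardize_exposure",
                   standardize_log_exposure(cohort$exposure))
    strata <- list(all = rep(TRUE, nrow(cohort)))
    if (config$by_sex && "sex" %in% names(cohort)) {
      for (s in levels(factor(cohort$sex))) {
        strata[[s]] <- cohort$sex == s
      }
    }
    for (oc in outcomes) {
      for (preset in config$adjustments) {
        cols <- adjustment_columns(preset, cohort)
        # OLS walks the confounder-adjustment rungs; 2SLS the ancestry rungs
        ols_preset <- preset %in% c("crude", "sociodemographic", "full")
        iv_preset <- preset %in% c("crude", "pca")
        for (st in names(strata)) {
          keep <- strata[[st]]
          cols_st <- if (st == "all") cols else setdiff(cols, "sex")
          covs <- if (length(cols_st)) {
            droplevels(as.data.frame(cohort)[keep, cols_st, drop = FALSE])
          } else {
            NULL
          }
          y <- cohort[[oc]][keep]
          zz <- z[keep]
          g <- cohort$genotype[keep]
          if (want("ols") && ols_preset) {
            res <- run_stage("ols_fit", ols_fit(y, zz, covs))
            note("OLS %s/%s/%s: n = %d", oc, preset, st, res$n)
            add_block(oc, "OLS", preset, st, res)
          }
          if (want("tsls") && iv_preset) {
            res <- run_stage("tsls_fit", tsls_fit(y, zz, g, covs))
            if (res$diagnostics$f_statistic < 10) {
              note("WARNING weak instrument %s/%s/%s: F = %.2f",
                   oc, preset, st, res$diagnostics$f_statistic)
            }
            note("2SLS %s/%s/%s: n = %d (first-stage F = %.1f, R2 = %.4f)",
                 oc, preset, st, res$estimate$n, res$diagnostics$f_statistic,
                 res$diagnostics$r2)
            add_block(oc, "2SLS", preset, st, res)
          }
          if (want("dwh") && iv_preset) {
            res <- run_stage("dwh_test", dwh_test(y, zz, g, covs))
            note("DWH %s/%s/%s: p = %.4g", oc, preset, st, res$p_value)
            add_block(oc, "DWH", preset, st, res)
          }
        }
      }
    }
    if (want("balance")) {
      pcs <- grep("^pc[0-9]+$", names(cohort), value = TRUE)
      anc <- if (length(pcs)) as.data.frame(cohort)[, pcs, drop = FALSE] else NULL
      for (cv in intersect(c("sex", "skin"), names(cohort))) {
        res <- run_stage("covariate_balance",
                         covariate_balance(cohort$genotype, cohort[[cv]],
                                           ancestry = anc, name = cv))
        note("balance %s: p = %.3g (unadjusted), p = %.3g (adjusted)",
             cv, res$p_unadjusted, res$p_adjusted)
        add_block("genotype", "balance", cv, "all", res)
      }
    }
  }

  if (two_sample) {
    panels <- run_stage("load_panels", {
      if (!is.null(config$panel_files)) {
        lapply(config$panel_files, read_panel_tsv)
      } else {
        pc <- config$panel_config %||% two_sample_config(seed = config$seed)
        out <- list()
        for (i in seq_along(outcomes)) {
          pci <- pc
          pci$seed <- config$seed + (i - 1L)
          out[[outcomes[i]]] <- simulate_two_sample_summary(pci)
        }
        out
      }
    })
    panels <- panels[intersect(outcomes, names(panels))]
    data_used$panels <- list()
    for (oc in names(panels)) {
      panel <- run_stage("harmonize", suppressMessages(harmonize(panels[[oc]])))
      n_pal <- sum(panel$palindromic)
      if (n_pal) note("WARNING %d palindromic SNP(s) retained in %s panel", n_pal, oc)
      note("panel %s: k = %d SNPs after harmonization", oc, nrow(panel))
      data_used$panels[[oc]] <- panel
      if (want("meta")) {
        res <- run_stage("meta_exposure",
                         fixed_effects_meta(panel$beta_exp, panel$se_exp))
        note("meta exposure (%s panel): k = %d, I2 = %.1f%%", oc, res$k, res$i2)
        add_block(oc, "meta_exposure", "crude", "all", res)
        res <- run_stage("meta_outcome",
                         fixed_effects_meta(panel$beta_out, panel$se_out))
        note("meta outcome %s: k = %d, I2 = %.1f%%", oc, res$k, res$i2)
        add_block(oc, "meta_outcome", "crude", "all", res)
      }
      if (want("ivw")) {
        target <- config$single_snp %||%
          panel$snp[which.max(abs(panel$beta_exp))]
        rec <- panel[panel$snp == target, , drop = FALSE]
        if (nrow(rec) != 1) {
          stop(sprintf("pipeline stage 'ivw_single' failed: SNP '%s' not found in %s panel",
                       target, oc), call. = FALSE)
        }
        res <- run_stage("ivw_single", ivw_single(rec))
        note("IVW single %s (%s): 1 SNP", oc, target)
        add_block(oc, "IVW_single", "crude", "all", res)
        if (nrow(panel) >= 2) {
          res <- run_stage("ivw_multi", ivw_multi(panel))
          note("IVW multi %s: k = %d SNPs", oc, res$n_snps)
          add_block(oc, "IVW_multi", "crude", "all", res)
        }
      }
      if (want("egger")) {
        res <- run_stage("egger_regression",
                         egger_regression(panel, n_boot = config$n_boot,
                                          seed = config$seed))
        note("MR-Egger %s: k = %d SNPs, %d bootstrap iterations",
             oc, res$n_snps, res$n_boot)
        add_block(oc, "Egger", "crude", "all", res)
      }
    }
  }

  structure(
    list(blocks = blocks,
         provenance = list(
           config_hash = rlang::hash(unclass(config)),
           seed = config$seed,
           version = as.character(packageVersion("hcymr"))),
         log = log,
         data = data_used),
    class = "mr_report"
  )
}

#' @export
print.mr_report <- function(x, ...) {
  cat(sprintf("MR analysis report: %d blocks (config %s, seed %d)\n",
              length(x$blocks), substr(x$provenance$config_hash, 1, 8),
              x$provenance$seed))
  for (key in names(x$blocks)) cat(" -", key, "\n")
  invisible(x)
}

block_row <- function(b) {
  r <- b$result
  if (inherits(r, "tsls_fit")) r <- r$estimate
  est <- function(f) if (!is.null(r[[f]])) r[[f]] else NA_real_
  data.frame(
    outcome = b$outcome, method = b$method, adjustment = b$adjustment,
    stratum = b$stratum,
    beta = est("beta"),
    se = est("se"),
    ci_low = est("ci_low"), ci_high = est("ci_high"),
    p_value = est("p_value"),
    stringsAsFactors = FALSE
  )
}

#' Flatten a report's estimate blocks into a table
#'
#' @param report An `mr_report`.
#' @return A data frame with one row per OLS/2SLS/IVW estimate block
#'   (columns `outcome method adjustment stratum beta se ci_low ci_high
#'   p_value`).
#' @export
report_estimates <- function(report) {
  keep <- Filter(function(b) {
    inherits(b$result, c("mr_regression", "tsls_fit", "mr_estimate"))
  }, report$blocks)
  out <- do.call(rbind, lapply(keep, block_row))
  rownames(out) <- NULL
  out
}

serialize_block <- function(b) {
  r <- b$result
  cls <- class(r)[1]
  flat <- rapply(unclass(r), identity, how = "list")
  list(outcome = b$outcome, method = b$method, adjustment = b$adjustment,
       stratum = b$stratum, result_class = cls, result = flat)
}

deserialize_block <- function(b) {
  r <- b$result
  # restore sub-structure classes
  if (b$result_class == "tsls_fit") {
    r$estimate <- structure(r$estimate, class = "mr_regression")
    r$diagnostics <- structure(r$diagnostics, class = "first_stage_diagnostics")
  }
  list(outcome = b$outcome, method = b$method, adjustment = b$adjustment,
       stratum = b$stratum,
       result = structure(r, class = b$result_class))
}

#' Write a report to JSON and read it back
#'
#' Serialization is lossless for every numeric in the report (full-precision
#' JSON), so `read_report(write_report(r, p))` reproduces the result blocks.
#'
#' @param report An `mr_report`.
#' @param path Output JSON path.
#' @return `write_report()`: the path, invisibly. `read_report()`: an
#'   `mr_report` (without the bulky `data` element).
#' @export
write_report <- function(report, path) {
  obj <- list(
    provenance = report$provenance,
    log = report$log,
    blocks = lapply(report$blocks, serialize_block)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  blocks <- lapply(obj$blocks, deserialize_block)
  structure(
    list(blocks = blocks,
         provenance = obj$provenance,
         log = unlist(obj$log) %||% character(0),
         data = list()),
    class = "mr_report"
  )
}
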