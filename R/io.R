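#' Read and write cohort tables
#'
#' The cohort dialect is tab-delimited text with a header row and at least
#' the columns `iid genotype exposure sbp dbp`; any further columns are kept
#' as covariates/ancestry scores. Missing values are forbidden. When the two
#' raw blood-pressure readings are stored as `sbp1 sbp2` (and/or
#' `dbp1 dbp2`), the reader averages them into `sbp`/`dbp` — mirroring a
#' protocol in which pressure is measured at the start and end of the
#' interview and the mean of the two readings is analysed.
#'
#' @param path File path.
#' @return `read_cohort_tsv()`: a `cohort_table` data frame.
#' @export
read_cohort_tsv <- function(path) {
  d <- read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
  for (v in c("sbp", "dbp")) {
    v1 <- paste0(v, "1"); v2 <- paste0(v, "2")
    if (all(c(v1, v2) %in% names(d)) && !v %in% names(d)) {
      d[[v]] <- (d[[v1]] + d[[v2]]) / 2
    }
  }
  need <- c("iid", "genotype", "exposure", "sbp", "dbp")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("cohort file is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(d)) {
    stop("cohort fixtures must not contain missing values", call. = FALSE)
  }
  if (!all(d$genotype %in% 0:2)) {
    stop("genotype dosage must be 0, 1 or 2", call. = FALSE)
  }
  if (any(d$exposure <= 0)) stop("exposure must be positive", call. = FALSE)
  for (v in intersect(c("sex", "skin"), names(d))) d[[v]] <- factor(d[[v]])
  class(d) <- c("cohort_table", "data.frame")
  d
}

#' @rdname read_cohort_tsv
#' @param cohort A `cohort_table`.
#' @return `write_cohort_tsv()`: the path, invisibly.
#' @export
write_cohort_tsv <- function(cohort, path) {
  stopifnot(!anyNA(cohort))
  write_tsv_full_precision(as.data.frame(cohort), path)
  invisible(path)
}

# Doubles are written with 17 significant digits so that write -> read
# round-trips reproduce every value exactly.
write_tsv_full_precision <- function(d, path) {
  for (j in seq_along(d)) {
    if (is.double(d[[j]])) d[[j]] <- sprintf("%.17g", d[[j]])
  }
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read and write summary-statistic panels
#'
#' The panel dialect is tab-delimited text with header
#' `snp effect_allele other_allele beta_exp se_exp beta_out se_out`
#' (optional `gene`). `read_panel_wide()` joins separate exposure and
#' outcome files on `snp` + alleles, re-orienting outcome records whose
#' effect allele is the exposure file's other allele.
#'
#' @param path File path.
#' @return A `summary_panel` data frame.
#' @export
read_panel_tsv <- function(path) {
  d <- read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
  as_summary_panel(d)
}

#' @rdname read_panel_tsv
#' @param panel A `summary_panel`.
#' @export
write_panel_tsv <- function(panel, path) {
  write_tsv_full_precision(as.data.frame(panel), path)
  invisible(path)
}

#' @rdname read_panel_tsv
#' @param exposure_path,outcome_path Paths to exposure-side and outcome-side
#'   association files, each with columns
#'   `snp effect_allele other_allele beta se`.
#' @export
read_panel_wide <- function(exposure_path, outcome_path) {
  ex <- read.delim(exposure_path, sep = "\t", stringsAsFactors = FALSE)
  ou <- read.delim(outcome_path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("snp", "effect_allele", "other_allele", "beta", "se")
  stopifnot(all(need %in% names(ex)), all(need %in% names(ou)))
  m <- merge(ex, ou, by = "snp", suffixes = c("_exp", "_out"))
  same <- m$effect_allele_exp == m$effect_allele_out &
    m$other_allele_exp == m$other_allele_out
  swapped <- m$effect_allele_exp == m$other_allele_out &
    m$other_allele_exp == m$effect_allele_out
  if (any(!same & !swapped)) {
    stop("allele mismatch for SNP(s): ",
         paste(m$snp[!same & !swapped], collapse = ", "), call. = FALSE)
  }
  m$beta_out[swapped] <- -m$beta_out[swapped]
  out <- data.frame(
    snp = m$snp,
    effect_allele = m$effect_allele_exp,
    other_allele = m$other_allele_exp,
    beta_exp = m$beta_exp, se_exp = m$se_exp,
    beta_out = m$beta_out, se_out = m$se_out,
    stringsAsFactors = FALSE
  )
  if ("gene" %in% names(ex)) out$gene <- ex$gene[match(out$snp, ex$snp)]
  as_summary_panel(out)
}

#' Read an analysis configuration from YAML or JSON
#'
#' The document mirrors the [analysis_config()] arguments; nested
#' `cohort_config` / `panel_config` blocks mirror [cohort_config()] and
#' [two_sample_config()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `analysis_config` object.
#' @export
read_mr_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$cohort_config)) {
    raw$cohort_config <- do.call(cohort_config, raw$cohort_config)
  }
  if (!is.null(raw$panel_config)) {
    raw$panel_config <- do.call(two_sample_config, raw$panel_config)
  }
  do.call(analysis_config, raw)
}
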