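fig_device <- function() {
  if (isTRUE(capabilities("cairo")[[1]])) "svg" else "pdf"
}

save_fig <- function(plot, path_stub, width = 7, height = 5) {
  ext <- fig_device()
  path <- paste0(path_stub, ".", ext)
  dev <- if (ext == "svg") grDevices::svg else grDevices::pdf
  ggplot2::ggsave(path, plot, width = width, height = max(height, 3),
                  limitsize = FALSE, device = dev)
  path
}

#' Render a report to result files and figures
#'
#' Writes the machine-readable results (`results/report.json`, a lossless
#' serialization of every block, and `results/estimates.tsv`, the flat
#' estimate table) plus the standard figures of an MR analysis:
#'
#' * a coefficient dot-plot with 95% CIs for every OLS/2SLS/IVW/Egger
#'   estimate (`figures/coefficients`),
#' * a per-SNP forest plot per outcome with the pooled fixed-effects row and
#'   an I-squared annotation (`figures/forest_<outcome>`),
#' * a scatter of SNP-outcome against SNP-exposure betas with the IVW
#'   (through-origin, dashed) and MR-Egger (solid) fitted lines
#'   (`figures/egger_<outcome>`),
#'
#' and the run log (`logs/run.log`). Figures are SVG where cairo is
#' available, PDF otherwise, and are deterministic given the report (fixed
#' ordering, no jitter).
#'
#' @param report An `mr_report` from [run_pipeline()].
#' @param output_dir Output directory (created if needed).
#' @return Invisibly, a character vector of the files written.
#' @export
render_report <- function(report, output_dir = "mr_output") {
  stopifnot(inherits(report, "mr_report"))
  if (!length(report$blocks)) stop("report is empty; nothing to render",
                                   call. = FALSE)
  for (d in c("results", "figures", "logs")) {
    dir.create(file.path(output_dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  written <- character(0)
  jp <- file.path(output_dir, "results", "report.json")
  write_report(report, jp)
  written <- c(written, jp)

  est <- report_estimates(report)
  tp <- file.path(output_dir, "results", "estimates.tsv")
  write.table(est, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  written <- c(written, tp)

  lp <- file.path(output_dir, "logs", "run.log")
  writeLines(c(sprintf("config_hash: %s", report$provenance$config_hash),
               sprintf("seed: %s", report$provenance$seed),
               report$log), lp)
  written <- c(written, lp)

  if (nrow(est)) {
    est$label <- paste(est$method, est$adjustment, est$stratum, sep = " / ")
    est$label <- factor(est$label, levels = rev(unique(est$label)))
    p <- ggplot2::ggplot(est, ggplot2::aes(x = .data$beta, y = .data$label)) +
      ggplot2::geom_vline(xintercept = 0, linetype = "dotted", colour = "grey50") +
      ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                           xmax = .data$ci_high),
                              height = 0.2) +
      ggplot2::geom_point(size = 2) +
      ggplot2::facet_wrap(~outcome, ncol = 1, scales = "free_y") +
      ggplot2::labs(x = "mm Hg per SD log homocysteine", y = NULL,
                    title = "Causal and observational estimates") +
      ggplot2::theme_bw()
    written <- c(written, save_fig(p, file.path(output_dir, "figures",
                                                "coefficients"),
                                   height = 2 + 0.4 * nrow(est)))
  }

  for (oc in names(report$data$panels %||% list())) {
    panel <- report$data$panels[[oc]]
    meta_key <- paste(oc, "meta_outcome", "crude", "all", sep = "|")
    meta <- report$blocks[[meta_key]]$result
    fd <- data.frame(
      label = paste0(panel$snp, " (", panel$gene %||% "", ")"),
      beta = panel$beta_out,
      lo = panel$beta_out - qnorm(0.975) * panel$se_out,
      hi = panel$beta_out + qnorm(0.975) * panel$se_out,
      pooled = FALSE, stringsAsFactors = FALSE
    )
    if (!is.null(meta)) {
      fd <- rbind(fd, data.frame(label = "Pooled (fixed effects)",
                                 beta = meta$pooled_beta,
                                 lo = meta$ci_low, hi = meta$ci_high,
                                 pooled = TRUE))
    }
    fd$label <- factor(fd$label, levels = rev(fd$label))
    p <- ggplot2::ggplot(fd, ggplot2::aes(x = .data$beta, y = .data$label,
                                          colour = .data$pooled)) +
      ggplot2::geom_vline(xintercept = 0, linetype = "dotted", colour = "grey50") +
      ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                              height = 0.2) +
      ggplot2::geom_point(shape = 18, size = 2.5) +
      ggplot2::scale_colour_manual(values = c(`FALSE` = "black",
                                              `TRUE` = "firebrick"),
                                   guide = "none") +
      ggplot2::labs(x = sprintf("%s change per effect allele (mm Hg)",
                                toupper(oc)),
                    y = NULL,
                    title = sprintf("Per-SNP associations with %s", toupper(oc)),
                    subtitle = if (!is.null(meta)) {
                      sprintf("Fixed-effects pooled = %.2f; I² = %.0f%% (Q = %.1f, p = %.2g)",
                              meta$pooled_beta, meta$i2, meta$q_statistic,
                              meta$p_heterogeneity)
                    } else NULL) +
      ggplot2::theme_bw()
    written <- c(written, save_fig(p, file.path(output_dir, "figures",
                                                paste0("forest_", oc)),
                                   height = 2 + 0.25 * nrow(fd)))

    ivw_key <- paste(oc, "IVW_multi", "crude", "all", sep = "|")
    egg_key <- paste(oc, "Egger", "crude", "all", sep = "|")
    ivw <- report$blocks[[ivw_key]]$result
    egg <- report$blocks[[egg_key]]$result
    if (!is.null(ivw) || !is.null(egg)) {
      sp <- data.frame(x = panel$beta_exp, y = panel$beta_out,
                       se = panel$se_out)
      p <- ggplot2::ggplot(sp, ggplot2::aes(x = .data$x, y = .data$y)) +
        ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
        ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$y - .data$se,
                                            ymax = .data$y + .data$se),
                               width = 0, colour = "grey60") +
        ggplot2::geom_point() +
        ggplot2::labs(
          x = "SNP-homocysteine beta (SD log units per allele)",
          y = sprintf("SNP-%s beta (mm Hg per allele)", toupper(oc)),
          title = sprintf("IVW (dashed) and MR-Egger (solid) fits: %s",
                          toupper(oc))) +
        ggplot2::theme_bw()
      if (!is.null(ivw)) {
        p <- p + ggplot2::geom_abline(intercept = 0, slope = ivw$beta,
                                      linetype = "dashed")
      }
      if (!is.null(egg)) {
        p <- p + ggplot2::geom_abline(intercept = egg$intercept,
                                      slope = egg$slope)
      }
      written <- c(written, save_fig(p, file.path(output_dir, "figures",
                                                  paste0("egger_", oc))))
    }
  }
  invisible(written)
}
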