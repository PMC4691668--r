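#!/usr/bin/env Rscript
# Stage 1: generate the study inputs.
#
# Builds (a) an individual-level cohort calibrated to the emulated study --
# n = 3701 complete cases, T-allele frequency 0.31, first-stage R2 5.3%,
# confounding worth about +1 mm Hg/SD on the observational slope -- and
# (b) 18-SNP two-sample summary panels for SBP and DBP with directional
# pleiotropy, then writes both as tab-delimited files under results/data/.

suppressPackageStartupMessages(library(hcymr))
set_dir <- "results/data"
dir.create(set_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 20240101L

co <- simulate_cohort(cohort_config(n_individuals = 3701, target_r2 = 0.053,
                                    causal_beta = 0, seed = seed))
write_cohort_tsv(co, file.path(set_dir, "cohort.tsv"))

geno <- prop.table(table(factor(co$genotype, levels = 0:2)))
cat(sprintf("cohort: n = %d; genotype frequencies CC/CT/TT = %.1f/%.1f/%.1f%%\n",
            nrow(co), 100 * geno[1], 100 * geno[2], 100 * geno[3]))
cat(sprintf("        (Hardy-Weinberg at T-allele frequency %.3f expects %.1f/%.1f/%.1f%%)\n",
            0.31, 100 * 0.69^2, 100 * 2 * 0.31 * 0.69, 100 * 0.31^2))
cat(sprintf("        exposure geometric mean %.1f umol/L; SBP %.1f, DBP %.1f mm Hg\n",
            exp(mean(log(co$exposure))), mean(co$sbp), mean(co$dbp)))

for (oc in c("sbp", "dbp")) {
  pan <- simulate_two_sample_summary(two_sample_config(
    causal_beta = 0.5, pleiotropy_mean = 0.1, pleiotropy_sd = 0.05,
    seed = seed + match(oc, c("sbp", "dbp"))))
  write_panel_tsv(pan, file.path(set_dir, sprintf("panel_%s.tsv", oc)))
  cat(sprintf("panel %s: %d SNPs, %d stored on the exposure-decreasing allele\n",
              oc, nrow(pan), sum(pan$beta_exp < 0)))
}
cat("wrote", set_dir, "\n")
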