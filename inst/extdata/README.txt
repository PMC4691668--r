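All files in this directory are SYNTHETIC, generated by the package's own
seeded simulators (simulate_cohort / simulate_two_sample_summary). They are
format examples and test inputs only; they contain no real cohort or
consortium data.

synthetic_cohort_200.tsv
    200-individual cohort table (tab-delimited): iid, genotype dosage
    (0/1/2 T alleles), exposure (homocysteine, umol/L), sbp, dbp (mm Hg),
    sex, skin, pc1 (ancestry score), confounder (latent, kept for checks),
    stratum. Generated with cohort_config(n_individuals = 200,
    target_r2 = 0.053, seed = 2024).

synthetic_panel_18snp_sbp.tsv / synthetic_panel_18snp_dbp.tsv
    18-SNP two-sample summary panels (tab-delimited): snp, effect_allele,
    other_allele, beta_exp/se_exp (SD log-exposure per allele),
    beta_out/se_out (mm Hg per allele), gene. Generated with
    two_sample_config(causal_beta = 0.5, pleiotropy_mean = 0.1,
    pleiotropy_sd = 0.05, seed = 2025/2026). A fraction of records is
    deliberately stored on the exposure-decreasing allele so that
    harmonize() has work to do.
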