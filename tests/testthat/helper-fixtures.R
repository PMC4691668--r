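# Small, fast fixture builders shared across the suite. All randomness is
# seeded through the generator configs so tests are reproducible.

quick_cohort <- function(seed, n = 500, ...) {
  simulate_cohort(cohort_config(n_individuals = n, seed = seed, ...))
}

quick_panel <- function(seed, ...) {
  simulate_two_sample_summary(two_sample_config(seed = seed, ...))
}

harmonized_panel <- function(seed, ...) {
  suppressMessages(harmonize(quick_panel(seed, ...)))
}

# Brute-force Wald ratio from raw moments: the independent oracle for
# exactly-identified IV with no covariates.
wald_oracle <- function(g, x, y) {
  cov(g, y) / cov(g, x)
}
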