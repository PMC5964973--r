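# Blood-pressure method-comparison summary used throughout: 85 paired
# differences (observer minus machine), mean -16.29 mmHg, SD 19.61 mmHg.
bp_summary <- function() sample_summary(85, -16.29, 19.61)

# Random but reproducible summaries for property-style loops.
random_summaries <- function(k, seed = 42) {
  set.seed(seed)
  lapply(seq_len(k), function(i) {
    sample_summary(sample(5:100, 1), rnorm(1, 0, 20), runif(1, 0.5, 25))
  })
}

# Monte-Carlo standard error of an empirical quantile at probability prob,
# via the asymptotic formula se = sqrt(prob (1 - prob) / reps) / f(q).
quantile_mc_se <- function(prob, reps, density_at_q) {
  sqrt(prob * (1 - prob) / reps) / density_at_q
}

# Draw `reps` values of the sample SD of a normal(0, sigma^2) sample of
# size n, through its exact chi-square representation.
draw_sample_sd <- function(reps, n, sigma = 1) {
  sigma * sqrt(rchisq(reps, df = n - 1) / (n - 1))
}
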