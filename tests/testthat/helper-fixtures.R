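# shared fixtures: the four-condition response-time reference sample and
# small helpers used across test files

worked_means <- c(593, 626, 630, 756)
worked_a <- c(-0.190, -0.973, 0.823, 0.600)

worked_sample <- function(n = 10L) condition_sample_from_means(worked_means, n = n)

fig3_env <- function() {
  design_environment(4, 10, 100, mu = c(600, 620, 640, 660))
}

# a small noisy balanced sample with known structure
noisy_sample <- function(p = 4, n = 10, sigma = 100, seed = 42,
                         mu = seq(600, by = 20, length.out = p)) {
  generate_dataset(design_environment(p, n, sigma, mu = mu), seed = seed)
}

# Monte-Carlo standard errors of the per-estimator mean SSE
mc_se <- function(sim) {
  apply(sim$per_rep_sse, 2, stats::sd) / sqrt(nrow(sim$per_rep_sse))
}
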