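# Shared fixture builders for the test suite.  Everything is generated in
# code; no data files.

# 1-D intensity values from a labelled Gaussian mixture
make_mixture_data <- function(n, means, sds, freqs, seed) {
  set.seed(seed)
  cls <- sample(seq_along(means), n, replace = TRUE, prob = freqs)
  list(x = stats::rnorm(n, means[cls], sds[cls]), classes = cls - 1L)
}

# hand Bayes-rule posteriors for fixed mixture parameters (oracle,
# independent of the EM code path)
bayes_posteriors <- function(x, pi_k, mu, sigma2) {
  d <- vapply(seq_along(mu), function(k)
    pi_k[k] * stats::dnorm(x, mu[k], sqrt(sigma2[k])), numeric(length(x)))
  d <- matrix(d, length(x), length(mu))
  d / rowSums(d)
}

# textbook Pearson chi-square on a 2 x K count table (oracle)
pearson_chisq_2xK <- function(a, b) {
  tab <- rbind(a, b)
  exp <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - exp)^2 / exp)
}

# small spiked two-cohort study used by pipeline tests
small_spiked_config <- function(seed = 42, beta = 0.25, n_cnvr = 8,
                                sizes = c(400, 350)) {
  sim_config(cohorts = c("A", "B"), sizes = sizes,
             noise_sd = c(0.08, 0.12), probes_per_cnvr = c(10, 8),
             dialect = c("LRR", "LRR"), child = c(FALSE, FALSE),
             family_cohort = "A", n_cnvr = n_cnvr,
             spike = list(cnvr = "CNVR001.1", trait = "FEV1", beta = beta),
             seed = seed)
}
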