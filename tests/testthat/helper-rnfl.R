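# Shared test helpers.

# Small sampler configuration for quick fits in unit tests.
quick_config <- function(seed, chains = 2L, adapt = 300L, warmup = 200L,
                         draws = 300L, ...) {
  sampler_config(chains = chains, adapt = adapt, warmup = warmup,
                 draws = draws, seed = seed, ...)
}

# Small synthetic cohort.
tiny_cohort <- function(seed = 1, n_eyes = 12, sectors = "G", ...) {
  generate_cohort(cohort_design(n_eyes = n_eyes, sectors = sectors, ...),
                  seed = seed)
}

# Hand-built rnfl_fit whose "posterior draws" are independent normals around
# known centers; lets summary-layer functions be tested against exact
# expectations without running a sampler.
fake_fit <- function(n_eyes = 4, n_draws = 400, n_chains = 2, seed = 42,
                     mu = c(60, 64, -0.7, -0.45, log(2), log(2.5)),
                     beta_centers = NULL, sd = 0.05, sector = "G") {
  eyes <- sprintf("eye%02d", seq_len(n_eyes))
  if (is.null(beta_centers)) {
    beta_centers <- cbind(rep(mu[3], n_eyes), rep(mu[4], n_eyes))
  }
  centers <- c(mu, 0.16, 0.16, 0.3)
  names(centers) <- c(sprintf("mu[%d]", 1:6), "Sigma[5,5]", "Sigma[6,6]",
                      "rho")
  for (k in 1:6) {
    for (i in seq_len(n_eyes)) {
      v <- switch(k, mu[1], mu[2], beta_centers[i, 1], beta_centers[i, 2],
                  mu[5], mu[6])
      centers[sprintf("b[%d,%d]", i, k)] <- v
    }
  }
  samples <- withr::with_seed(seed, coda::mcmc.list(lapply(
    seq_len(n_chains),
    function(ch) {
      m <- matrix(
        stats::rnorm(n_draws * length(centers),
                     mean = rep(centers, each = n_draws), sd = sd),
        nrow = n_draws
      )
      colnames(m) <- names(centers)
      coda::mcmc(m)
    }
  )))
  fit <- structure(
    list(samples = samples, sector = sector, eyes = eyes,
         dropped_eyes = character(), n_paired = 0L, n_unpaired = 0L,
         priors = prior_spec(),
         config = sampler_config(chains = n_chains, adapt = 300L,
                                 warmup = 0L, draws = n_draws, seed = 1L)),
    class = "rnfl_fit"
  )
  fit$diagnostics <- diagnose(fit)
  fit
}
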