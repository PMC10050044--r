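# Shared fixtures for the acceptance-level checks.  The full-size recovery
# study (100 subjects x 80 trials, model 9) is expensive, so it is built
# once on first use and reused across test blocks.

recovery_cache <- new.env(parent = emptyenv())

# sampler settings for the full-size recovery fit: 4 chains, thinned to
# 2500 retained draws each from 7500 post-warmup iterations
recovery_control <- function() {
  sampler_control(chains = 4, adapt = 500, warmup = 500, iter = 2500,
                  thin = 3)
}

get_recovery_study <- function() {
  if (is.null(recovery_cache$study)) {
    recovery_cache$study <- simulate_study(nst_hyperparameters(),
                                           n_subjects = 100, seed = 2024)
  }
  recovery_cache$study
}

get_recovery_fit <- function() {
  if (is.null(recovery_cache$fit)) {
    st <- get_recovery_study()
    recovery_cache$fit <- sample_posterior(
      st$choices, model_spec(9), control = recovery_control(), seed = 2025
    )
  }
  recovery_cache$fit
}
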