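# Model suite: standardisation, catalogue, likelihoods, sampling and
# convergence diagnostics.

test_that("predictors standardise against the design-level grid", {
  z <- standardize_predictors(c(3, 6, 9, 12), c("20%", "40%", "60%", "80%"))
  expect_equal(z$reward_z, (c(3, 6, 9, 12) - 7.5) / sqrt(45 / 4),
               tolerance = 1e-12)
  expect_equal(z$reward_z[1], -1.3416408, tolerance = 1e-6)
  expect_equal(z$effort_z, z$reward_z, tolerance = 1e-12) # affine image grids
  expect_equal(z$reward_z2, z$reward_z^2)
  expect_equal(z$effort_z2, z$effort_z^2)
  expect_equal(sum(z$reward_z), 0)
  expect_error(standardize_predictors(5, "20%"), "out-of-grid")
  expect_error(standardize_predictors(3, "30%"), "out-of-grid")
  # numeric and labelled effort agree
  expect_equal(standardize_predictors(3, 80)$effort_z,
               standardize_predictors(3, "80%")$effort_z)
})

test_that("the catalogue holds exactly the twelve fixed/varying variants", {
  cat12 <- model_catalogue()
  expect_length(cat12, 12)
  expect_identical(vapply(cat12, `[[`, integer(1), "id"), 1:12)
  expect_identical(
    model_spec(9)$terms,
    c(intercept = "varying", reward = "varying", reward2 = "varying",
      effort = "varying")
  )
  expect_identical(model_spec(1)$terms, c(intercept = "fixed"))
  expect_identical(
    model_spec(7)$terms,
    c(intercept = "varying", reward = "varying", effort = "varying",
      effort2 = "varying")
  )
  expect_identical(model_spec(2)$terms,
                   c(intercept = "fixed", reward = "fixed", effort = "fixed"))
  # every varying term implies hyperparameters in the JAGS code
  code <- nstask:::jags_model_code(model_spec(9), nst_priors())
  expect_match(code, "mu_effort")
  expect_match(code, "sigma_reward2")
  expect_error(model_spec(13), "1\\.\\.12")
})

test_that("pointwise log-likelihood matches a direct Bernoulli oracle", {
  d <- make_tiny_dataset(n_subjects = 3, n_trials = 20)
  spec <- model_spec(9)
  params <- make_params(spec, S = 3, seed = 2)
  ll <- pointwise_log_likelihood(params, d, spec)
  expect_length(ll, nrow(d))
  # independent direct computation
  subj <- as.integer(factor(d$subject))
  p <- plogis(params$alpha[subj] + params$beta_reward[subj] * d$reward_z +
                params$beta_reward2[subj] * d$reward_z2 +
                params$beta_effort[subj] * d$effort_z)
  expect_equal(sum(ll), oracle_bernoulli_ll(d$accepted, p), tolerance = 1e-10)
  # constant p = 0.5 gives log(0.5) everywhere
  flat <- list(alpha = 0)
  ll0 <- pointwise_log_likelihood(flat, d, model_spec(1))
  expect_equal(ll0, rep(log(0.5), nrow(d)))
  expect_error(pointwise_log_likelihood(list(), d, model_spec(1)),
               "missing parameter: alpha")
})

test_that("model 9 at zero quadratic weight reproduces model 4's likelihood", {
  d <- make_tiny_dataset(n_subjects = 4, n_trials = 15)
  p9 <- make_params(model_spec(9), S = 4, seed = 3)
  p9$beta_reward2 <- rep(0, 4)
  p4 <- p9[c("alpha", "beta_reward", "beta_effort")]
  expect_equal(pointwise_log_likelihood(p9, d, model_spec(9)),
               pointwise_log_likelihood(p4, d, model_spec(4)))
  expect_true(all(names(model_spec(4)$terms) %in% names(model_spec(9)$terms)))
})

test_that("log posterior density equals an independent arithmetic oracle", {
  d <- make_tiny_dataset(n_subjects = 3, n_trials = 10)
  spec <- model_spec(4)
  priors <- nst_priors()
  params <- make_params(spec, S = 3, seed = 4)
  lp <- log_posterior_density(params, d, spec, priors)
  # independent evaluation term by term
  oracle <- 0
  for (term in c("intercept", "reward", "effort")) {
    par <- if (term == "intercept") "alpha" else paste0("beta_", term)
    mu <- params[[paste0("mu_", term)]]
    sg <- params[[paste0("sigma_", term)]]
    scale <- if (term == "intercept") 1.5 else 1
    oracle <- oracle + sum(dnorm(params[[par]], mu, sg, log = TRUE)) +
      dnorm(mu, 0, scale, log = TRUE) +
      log(2) + dnorm(sg, 0, 1, log = TRUE)
  }
  subj <- as.integer(factor(d$subject))
  p <- plogis(params$alpha[subj] + params$beta_reward[subj] * d$reward_z +
                params$beta_effort[subj] * d$effort_z)
  oracle <- oracle + oracle_bernoulli_ll(d$accepted, p)
  expect_equal(lp, oracle, tolerance = 1e-10)
  # zero-data dataset: prior only
  lp0 <- log_posterior_density(params, d[0, ], spec, priors)
  expect_equal(lp0, oracle - oracle_bernoulli_ll(d$accepted, p),
               tolerance = 1e-10)
  # duplicated rows double the likelihood part exactly
  lp2 <- log_posterior_density(params, rbind(d, d), spec, priors)
  expect_equal(lp2 - lp0, 2 * (lp - lp0), tolerance = 1e-10)
  # non-positive population SD is a rejected state, not an error
  bad <- params
  bad$sigma_effort <- 0
  expect_identical(log_posterior_density(bad, d, spec, priors), -Inf)
})

test_that("prior draws match the prior's analytic moments", {
  pr <- sample_prior(model_spec(9), nst_priors(), n_draws = 40000, seed = 6)
  expect_lt(abs(mean(pr$mu_intercept)), 4 * 1.5 / sqrt(40000))
  expect_lt(abs(sd(pr$mu_intercept) - 1.5), 0.03)
  expect_lt(abs(sd(pr$mu_effort) - 1), 0.02)
  # half-normal(1): mean sqrt(2/pi)
  expect_lt(abs(mean(pr$sigma_effort) - sqrt(2 / pi)), 0.02)
})

test_that("split R-hat and ESS behave on constructed chains", {
  set.seed(31)
  good <- array(rnorm(4000), dim = c(1000, 4, 1),
                dimnames = list(NULL, NULL, "theta"))
  dg <- compute_diagnostics(good)
  expect_true(dg$pass)
  expect_lt(dg$max_rhat, 1.01)
  expect_gt(dg$min_ess, 400)
  # i.i.d. draws: ESS should be near the sample size
  expect_gt(dg$min_ess, 2500)

  shifted <- good
  shifted[, 2, 1] <- shifted[, 2, 1] + 5
  dg2 <- compute_diagnostics(shifted)
  expect_false(dg2$pass)
  expect_gt(dg2$max_rhat, 1.5)

  const <- array(1, dim = c(100, 4, 1), dimnames = list(NULL, NULL, "c"))
  dg3 <- compute_diagnostics(const)
  expect_false(dg3$pass)
  expect_true(is.na(dg3$summary$rhat[1]))

  expect_error(compute_diagnostics(good[, 1, , drop = FALSE]),
               "single chain")
})

test_that("in-package diagnostics track coda on autocorrelated chains", {
  set.seed(32)
  arr <- array(NA_real_, dim = c(1500, 4, 1),
               dimnames = list(NULL, NULL, "x"))
  for (ch in 1:4) arr[, ch, 1] <- as.numeric(arima.sim(list(ar = 0.7), 1500))
  dg <- compute_diagnostics(arr)
  cl <- coda::mcmc.list(lapply(1:4, function(ch) coda::mcmc(arr[, ch, 1])))
  ess_coda <- unname(coda::effectiveSize(cl))
  # same order of magnitude; both should land near N*(1-phi)/(1+phi)
  expect_gt(dg$summary$ess, 0.5 * ess_coda)
  expect_lt(dg$summary$ess, 2.0 * ess_coda)
  expect_lt(dg$summary$rhat, 1.02)
})

test_that("posterior sampling is deterministic and recovers a fixed intercept", {
  st <- simulate_study(nst_hyperparameters(), 8, seed = 13)
  d <- st$choices
  fit <- sample_posterior(d, model_spec(1), control = tiny_control(), seed = 7)
  fit2 <- sample_posterior(d, model_spec(1), control = tiny_control(), seed = 7)
  expect_identical(fit$draws, fit2$draws)
  fit3 <- sample_posterior(d, model_spec(1), control = tiny_control(), seed = 8)
  expect_false(identical(fit$draws, fit3$draws))
  # model 1: acceptance-rate check on the probability scale
  p_post <- plogis(mean(as.matrix(fit)[, "alpha"]))
  emp <- mean(d$accepted)
  expect_lt(abs(p_post - emp), 3 * sqrt(emp * (1 - emp) / nrow(d)) + 0.01)
  expect_error(sample_posterior(d[0, ], model_spec(1)), "empty")
})

test_that("draws expose the documented parameter names and serialise to CSV", {
  st <- simulate_study(nst_hyperparameters(), 5, seed = 14)
  fit <- sample_posterior(st$choices, model_spec(10),
                          control = tiny_control(chains = 2), seed = 9)
  expect_true(all(c("mu_intercept", "sigma_intercept", "mu_reward2",
                    "sigma_reward2", "mu_effort", "sigma_effort",
                    "alpha[1]", "beta_reward2[5]", "beta_effort[3]")
                  %in% fit$params))
  f <- withr::local_tempfile(fileext = ".csv")
  write_draws(fit, f)
  long <- read_draws(f)
  expect_identical(names(long), c("chain", "iteration", "parameter", "value"))
  expect_identical(nrow(long), length(fit$draws))
  one <- long[long$parameter == "mu_effort" & long$chain == 1, ]
  expect_equal(one$value, fit$draws[, 1, "mu_effort"], tolerance = 1e-12)
})

test_that("loglik_matrix reproduces pointwise_log_likelihood draw by draw", {
  st <- simulate_study(nst_hyperparameters(), 4, seed = 15)
  d <- st$choices
  fit <- sample_posterior(d, model_spec(4),
                          control = tiny_control(chains = 2), seed = 10)
  ll <- loglik_matrix(fit, d, max_draws = 50, chunk = 37)
  m <- as.matrix(fit)
  m <- m[round(seq(1, nrow(m), length.out = 50)), ]
  S <- fit$n_subjects
  for (dr in c(1, 25, 50)) {
    params <- list(
      alpha = unname(m[dr, paste0("alpha[", 1:S, "]")]),
      beta_reward = unname(m[dr, paste0("beta_reward[", 1:S, "]")]),
      beta_effort = unname(m[dr, paste0("beta_effort[", 1:S, "]")])
    )
    expect_equal(ll[dr, ],
                 pointwise_log_likelihood(params, d, model_spec(4)),
                 tolerance = 1e-10)
  }
})
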