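# Independent brute-force oracles used to freeze expected values.

# plain scan over adjacent pairs, written independently of count_switches
oracle_count_switches <- function(digits) {
  n <- 0L
  for (i in seq_len(length(digits) - 1L)) {
    if ((digits[i] %% 2) != (digits[i + 1] %% 2)) n <- n + 1L
  }
  n
}

# exhaustive enumeration over all 2^9 binary strings
oracle_parity_patterns <- function(k) {
  out <- character(0)
  for (code in 0:(2^9 - 1)) {
    bits <- as.integer(intToBits(code))[1:9]
    if (sum(bits) != 5L) next
    if (sum(abs(diff(bits))) != k) next
    out <- c(out, paste(ifelse(bits == 1L, "O", "E"), collapse = ""))
  }
  sort(out)
}

# naive loop-based WAIC, deliberately unvectorised
oracle_waic <- function(ll) {
  D <- nrow(ll)
  n <- ncol(ll)
  lppd_i <- numeric(n)
  p_i <- numeric(n)
  for (j in seq_len(n)) {
    lppd_i[j] <- log(sum(exp(ll[, j])) / D)
    p_i[j] <- stats::var(ll[, j])
  }
  waic_i <- -2 * (lppd_i - p_i)
  list(lppd = sum(lppd_i), p_waic = sum(p_i), waic = sum(waic_i),
       se_waic = sqrt(n * stats::var(waic_i)))
}

# direct Bernoulli log-likelihood via dbinom
oracle_bernoulli_ll <- function(y, p) {
  sum(stats::dbinom(y, 1, p, log = TRUE))
}

# small standardised dataset built by hand (no simulate_study machinery)
make_tiny_dataset <- function(n_subjects = 4, n_trials = 16, seed = 99) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    grid <- expand.grid(reward_points = c(3L, 6L, 9L, 12L),
                        effort_label = c("20%", "40%", "60%", "80%"),
                        stringsAsFactors = FALSE)
    rows <- do.call(rbind, lapply(seq_len(n_subjects), function(s) {
      g <- grid[sample.int(16, n_trials, replace = TRUE), ]
      g$subject <- s
      g
    }))
    z <- standardize_predictors(rows$reward_points, rows$effort_label)
    data.frame(
      subject = rows$subject,
      reward_points = rows$reward_points,
      effort_label = rows$effort_label,
      reward_z = z$reward_z, reward_z2 = z$reward_z2,
      effort_z = z$effort_z,
      accepted = rbinom(nrow(rows), 1, plogis(1 - 0.5 * z$effort_z))
    )
  })
}

# random full parameter assignment for a spec
make_params <- function(spec, S, seed = 1) {
  set.seed(seed)
  params <- list()
  for (term in names(spec$terms)) {
    par <- if (term == "intercept") "alpha" else paste0("beta_", term)
    if (spec$terms[[term]] == "varying") {
      params[[paste0("mu_", term)]] <- rnorm(1, 0, 0.5)
      params[[paste0("sigma_", term)]] <- runif(1, 0.2, 0.8)
      params[[par]] <- rnorm(S, params[[paste0("mu_", term)]],
                             params[[paste0("sigma_", term)]])
    } else {
      params[[par]] <- rnorm(1, 0, 0.5)
    }
  }
  params
}

# fast, small sampler settings for unit tests
tiny_control <- function(chains = 4) {
  sampler_control(chains = chains, adapt = 150, warmup = 150, iter = 250)
}
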