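# Synthetic cohort: simulated participants whose accept/reject choices
# follow the hierarchical logistic choice model and whose performance
# reproduces the statistical structure the downstream analysis assumes
# (calibrated time limits, ~90% success, times lengthening with switches).

CHOICES_HEADER <- c("subject", "trial", "reward_points", "effort_label",
                    "switch_count", "reward_z", "reward_z2", "effort_z",
                    "accepted", "success", "elapsed_ms", "allowed_time_ms")
TRUTH_HEADER <- c("subject", "alpha", "beta_reward", "beta_reward2",
                  "beta_effort", "allowed_time_ms")

#' Population hyperparameters for the synthetic cohort
#'
#' Choice-model block: population mean and SD (log-odds per standardised
#' predictor unit) of the subject-level intercept and of the linear reward,
#' quadratic reward and linear effort sensitivities.  Performance block:
#' per-digit base categorisation time (with a between-subject SD), a
#' per-switch time cost, a small per-point reward speeding, multiplicative
#' lognormal timing noise, a per-digit error probability, and a main-phase
#' practice speed-up relative to familiarisation.
#'
#' The defaults are chosen so that a default cohort reproduces the
#' qualitative calibration targets of the task: per-subject success rates
#' near 0.90 with small spread, allowed times around 8,950 ms, completion
#' times around 0.78-0.85 of the allowed limit, acceptance above 50% in
#' every reward-by-effort cell, and acceptance decreasing in effort more
#' shallowly at higher reward.
#'
#' @param alpha_mean,alpha_sd Intercept population mean and SD.
#' @param reward_mean,reward_sd Linear reward sensitivity mean and SD.
#' @param reward2_mean,reward2_sd Quadratic reward sensitivity mean and SD.
#' @param effort_mean,effort_sd Effort sensitivity mean and SD (negative
#'   mean = effort discounting).
#' @param base_ms Mean per-digit categorisation time, ms.
#' @param base_sd_ms Between-subject SD of the per-digit time, ms.
#' @param switch_cost_ms Additional time per parity switch, ms.
#' @param reward_speed_ms Speeding per offered reward point, ms.
#' @param time_noise_sd SD of the lognormal (sdlog) timing noise.
#' @param error_prob Per-digit probability of a wrong response.
#' @param practice_speedup Multiplier (< 1 speeds up) applied to main-phase
#'   completion times relative to familiarisation, emulating practice.
#' @param min_time_ms Floor on simulated completion times, ms.
#' @return List of class `nst_hyper`.
#' @export
nst_hyperparameters <- function(alpha_mean = 2.2, alpha_sd = 0.7,
                                reward_mean = 0.7, reward_sd = 0.4,
                                reward2_mean = -0.15, reward2_sd = 0.15,
                                effort_mean = -0.7, effort_sd = 0.45,
                                base_ms = 850, base_sd_ms = 170,
                                switch_cost_ms = 100, reward_speed_ms = 10,
                                time_noise_sd = 0.15, error_prob = 0.012,
                                practice_speedup = 0.9, min_time_ms = 1000) {
  h <- list(
    alpha_mean = alpha_mean, alpha_sd = alpha_sd,
    reward_mean = reward_mean, reward_sd = reward_sd,
    reward2_mean = reward2_mean, reward2_sd = reward2_sd,
    effort_mean = effort_mean, effort_sd = effort_sd,
    base_ms = base_ms, base_sd_ms = base_sd_ms,
    switch_cost_ms = switch_cost_ms, reward_speed_ms = reward_speed_ms,
    time_noise_sd = time_noise_sd, error_prob = error_prob,
    practice_speedup = practice_speedup, min_time_ms = min_time_ms
  )
  sds <- c(h$alpha_sd, h$reward_sd, h$reward2_sd, h$effort_sd,
           h$base_sd_ms, h$time_noise_sd)
  if (any(sds < 0)) stop_("population SDs must be non-negative")
  if (h$error_prob < 0 || h$error_prob > 1) {
    stop_("error_prob must lie in [0, 1]")
  }
  if (h$practice_speedup <= 0 || h$min_time_ms <= 0 || h$base_ms <= 0) {
    stop_("times and speed-up must be positive")
  }
  structure(h, class = "nst_hyper")
}

#' Draw a cohort of synthetic agents
#'
#' Each subject's four choice parameters are drawn independently from
#' Normal(population mean, population SD); the per-digit base time receives
#' between-subject jitter, other performance parameters are copied.  Each
#' subject is drawn on its own seed substream, so subject i's parameters do
#' not depend on the cohort size.
#'
#' @param hyper [nst_hyperparameters()] object.
#' @param n_subjects Number of agents (>= 1).
#' @param seed Optional master seed.
#' @return Data frame with one row per subject: choice parameters,
#'   performance parameters and `allowed_time_ms` (NA until the simulated
#'   familiarisation of [simulate_study()] calibrates it).
#' @export
draw_cohort <- function(hyper, n_subjects, seed = NULL) {
  stopifnot(inherits(hyper, "nst_hyper"))
  if (!is_count(n_subjects) || n_subjects < 1) {
    stop_("n_subjects must be a positive integer")
  }
  if (is.null(seed)) seed <- sample.int(2147483646L, 1L)
  rows <- lapply(seq_len(n_subjects), function(i) {
    with_seed(sub_seed(seed, i, 1L), {
      data.frame(
        subject = i,
        alpha = stats::rnorm(1, hyper$alpha_mean, hyper$alpha_sd),
        beta_reward = stats::rnorm(1, hyper$reward_mean, hyper$reward_sd),
        beta_reward2 = stats::rnorm(1, hyper$reward2_mean, hyper$reward2_sd),
        beta_effort = stats::rnorm(1, hyper$effort_mean, hyper$effort_sd),
        base_ms = max(stats::rnorm(1, hyper$base_ms, hyper$base_sd_ms), 300),
        switch_cost_ms = hyper$switch_cost_ms,
        reward_speed_ms = hyper$reward_speed_ms,
        time_noise_sd = hyper$time_noise_sd,
        error_prob = hyper$error_prob,
        practice_speedup = hyper$practice_speedup,
        min_time_ms = hyper$min_time_ms,
        allowed_time_ms = NA_real_
      )
    })
  })
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  out
}

#' Acceptance probability of the logistic choice model
#'
#' p = logistic(alpha + beta_reward * reward_z + beta_reward2 * reward_z^2 +
#' beta_effort * effort_z), evaluated at standardised predictor values.
#'
#' @param agent List or single data-frame row with `alpha`, `beta_reward`,
#'   `beta_reward2`, `beta_effort`.
#' @param reward_z,reward_z2,effort_z Standardised predictors (vectorised).
#' @return Probability in (0, 1).
#' @export
#' @examples
#' a <- list(alpha = 0, beta_reward = 0, beta_reward2 = 0, beta_effort = 0)
#' choice_probability(a, 1, 1, 1) # 0.5
choice_probability <- function(agent, reward_z, reward_z2, effort_z) {
  stopifnot(all(is.finite(reward_z)), all(is.finite(reward_z2)),
            all(is.finite(effort_z)))
  eta <- agent$alpha + agent$beta_reward * reward_z +
    agent$beta_reward2 * reward_z2 + agent$beta_effort * effort_z
  stats::plogis(eta)
}

#' Simulate performance on one accepted sequence
#'
#' Completion time is (9 * base + switch_cost * switches - speeding *
#' reward) * exp(Normal(0, time_noise_sd)) * speedup, floored at
#' `min_time_ms` and rounded to integer milliseconds.  Errors are
#' Binomial(9, per-digit error probability).
#'
#' @param agent One row of a [draw_cohort()] data frame (or equivalent list).
#' @param switch_count Parity switches of the sequence, 1..8.
#' @param reward_points Offered reward (0 for familiarisation trials, which
#'   carry no offer).
#' @param speedup Multiplier on the expected time (1 in familiarisation;
#'   the agent's `practice_speedup` in the main phase).
#' @return List with `n_errors` and `elapsed_ms`.
#' @export
simulate_performance <- function(agent, switch_count, reward_points = 0,
                                 speedup = 1) {
  if (!is_count(switch_count) || switch_count < 1 || switch_count > 8) {
    stop_("switch_count must be an integer in 1..8")
  }
  mean_ms <- 9 * agent$base_ms + agent$switch_cost_ms * switch_count -
    agent$reward_speed_ms * reward_points
  noise <- if (agent$time_noise_sd > 0) {
    exp(stats::rnorm(1, 0, agent$time_noise_sd))
  } else {
    1
  }
  t_ms <- max(agent$min_time_ms, mean_ms * speedup * noise)
  list(
    n_errors = stats::rbinom(1L, 9L, agent$error_prob),
    elapsed_ms = round(t_ms)
  )
}

#' Simulate a full study for a synthetic cohort
#'
#' For each agent: run the 32-trial familiarisation schedule through
#' [simulate_performance()] (with one retry of the phase if the 50% pass
#' rule fails), calibrate the allowed time via [calibrate_time_limit()],
#' then traverse a fresh 80-trial main schedule drawing accept/reject from
#' [choice_probability()] and, on acceptance, performance and
#' [score_trial()].  Rejected offers record no performance data.
#'
#' @param hyper [nst_hyperparameters()] object.
#' @param n_subjects Number of agents.
#' @param seed Master seed; per-subject substreams make subject i's data
#'   invariant to cohort size.
#' @param correct_only_calibration Passed to [calibrate_time_limit()].
#' @return List of class `nst_study`: `choices` (tidy trial data frame with
#'   the dataset CSV columns), `agents` (ground truth incl. calibrated
#'   `allowed_time_ms`), `excluded` (subjects failing familiarisation twice).
#' @export
#' @examples
#' st <- simulate_study(nst_hyperparameters(), n_subjects = 2, seed = 1)
#' head(st$choices)
simulate_study <- function(hyper, n_subjects, seed = NULL,
                           correct_only_calibration = FALSE) {
  agents <- draw_cohort(hyper, n_subjects, seed)
  seed <- attr(agents, "seed")
  excluded <- integer(0)
  per_subject <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    agent <- as.list(agents[i, ])
    res <- with_seed(sub_seed(seed, i, 2L), {
      fam <- run_familiarisation(agent)
      if (is.null(fam)) {
        NULL
      } else {
        allowed <- calibrate_time_limit(
          fam, correct_only = correct_only_calibration
        )$allowed_time_ms
        list(allowed = allowed, main = run_main_phase(agent, allowed))
      }
    })
    if (is.null(res)) {
      excluded <- c(excluded, i)
      next
    }
    agents$allowed_time_ms[i] <- res$allowed
    res$main$subject <- i
    per_subject[[i]] <- res$main
  }
  choices <- do.call(rbind, per_subject)
  if (!is.null(choices)) {
    choices <- choices[, CHOICES_HEADER]
    rownames(choices) <- NULL
  }
  structure(
    list(choices = choices,
         agents = agents[!(agents$subject %in% excluded), , drop = FALSE],
         excluded = excluded, hyper = hyper, seed = seed),
    class = "nst_study"
  )
}

# one familiarisation phase (with a single retry); NULL if excluded
run_familiarisation <- function(agent) {
  for (attempt in 1:2) {
    sched <- build_schedule("familiarisation")
    perf <- lapply(sched$switch_count, function(k) {
      simulate_performance(agent, k, reward_points = 0, speedup = 1)
    })
    fam <- data.frame(
      switch_count = sched$switch_count,
      n_errors = vapply(perf, `[[`, integer(1), "n_errors"),
      elapsed_ms = vapply(perf, `[[`, numeric(1), "elapsed_ms")
    )
    if (pass_familiarisation(fam)) return(fam)
  }
  NULL
}

run_main_phase <- function(agent, allowed) {
  sched <- build_schedule("main")
  z <- standardize_predictors(sched$reward_points, sched$effort_label)
  p <- choice_probability(agent, z$reward_z, z$reward_z2, z$effort_z)
  accepted <- stats::rbinom(nrow(sched), 1L, p)
  n <- nrow(sched)
  success <- rep(NA_integer_, n)
  elapsed <- rep(NA_real_, n)
  for (t in which(accepted == 1L)) {
    perf <- simulate_performance(agent, sched$switch_count[t],
                                 reward_points = sched$reward_points[t],
                                 speedup = agent$practice_speedup)
    outcome <- score_trial(perf$n_errors, perf$elapsed_ms, allowed)
    success[t] <- as.integer(outcome == "success")
    elapsed[t] <- perf$elapsed_ms
  }
  data.frame(
    trial = seq_len(n),
    reward_points = sched$reward_points,
    effort_label = sched$effort_label,
    switch_count = sched$switch_count,
    reward_z = z$reward_z,
    reward_z2 = z$reward_z2,
    effort_z = z$effort_z,
    accepted = accepted,
    success = success,
    elapsed_ms = elapsed,
    allowed_time_ms = allowed,
    stringsAsFactors = FALSE
  )
}

#' @export
print.nst_study <- function(x, ...) {
  cat(sprintf(
    "NST synthetic study: %d subject(s), %d trials, %d excluded\n",
    nrow(x$agents), if (is.null(x$choices)) 0L else nrow(x$choices),
    length(x$excluded)
  ))
  if (!is.null(x$choices)) {
    cat(sprintf("  mean acceptance %.3f; mean success (accepted) %.3f\n",
                mean(x$choices$accepted),
                mean(x$choices$success, na.rm = TRUE)))
  }
  invisible(x)
}
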